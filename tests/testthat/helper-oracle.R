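# Brute-force enumeration oracles, coded independently of the package
# internals: straight loops over the standard genetic code table.

.GC <- Biostrings::GENETIC_CODE
.NUCS <- c("A", "C", "G", "T")

oracle_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) {
    syn <- 0L; tot <- 0L
    for (nt in .NUCS[.NUCS != ch[p]]) {
      mut <- ch
      mut[p] <- nt
      mc <- paste(mut, collapse = "")
      if (.GC[[mc]] == "*") next
      tot <- tot + 1L
      if (.GC[[mc]] == .GC[[codon]]) syn <- syn + 1L
    }
    if (tot > 0L) s <- s + syn / tot
  }
  c(s = s, n = 3 - s)
}

.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

oracle_diffs <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  pos <- which(ca != cb)
  res <- c(sd = 0, nd = 0, transitions = 0, transversions = 0)
  if (length(pos) == 0L) return(res)
  purine <- function(x) x %in% c("A", "G")
  n_ok <- 0L
  acc <- res
  for (ord in .perms(pos)) {
    cur <- ca
    path <- res
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- cb[p]
      aa1 <- .GC[[paste(cur, collapse = "")]]
      aa2 <- .GC[[paste(nxt, collapse = "")]]
      if (aa2 == "*") { ok <- FALSE; break }
      if (aa1 == aa2) path["sd"] <- path["sd"] + 1
      else path["nd"] <- path["nd"] + 1
      if (purine(cur[p]) == purine(nxt[p])) {
        path["transitions"] <- path["transitions"] + 1
      } else {
        path["transversions"] <- path["transversions"] + 1
      }
      cur <- nxt
    }
    if (ok) { acc <- acc + path; n_ok <- n_ok + 1L }
  }
  if (n_ok == 0L) { res[] <- NA_real_; return(res) }
  acc / n_ok
}

# all sense codons, derived here rather than taken from the package
oracle_sense_codons <- local({
  all64 <- sort(as.vector(outer(outer(.NUCS, .NUCS, paste0), .NUCS, paste0)))
  all64[.GC[all64] != "*"]
})

# random in-frame sense-codon string
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(oracle_sense_codons, n_codons, replace = TRUE), collapse = "")
}
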