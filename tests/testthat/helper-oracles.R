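# Independent oracles and small fixture builders used across the suite.

rand_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
}

# brute-force O(n*m) window scan for recognition sites on both strands
oracle_find_sites <- function(seq, recognition) {
  m <- nchar(recognition)
  n <- nchar(seq)
  rc <- oracle_revcomp(recognition)
  out <- NULL
  for (p in seq_len(max(0L, n - m + 1L))) {
    win <- substr(seq, p, p + m - 1L)
    if (win == recognition)
      out <- rbind(out, data.frame(pos = p - 1L, strand = "+"))
    if (win == rc)
      out <- rbind(out, data.frame(pos = p - 1L, strand = "-"))
  }
  if (is.null(out))
    return(data.frame(pos = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# independent digestion oracle: per-site offset arithmetic yields top- and
# bottom-strand cut coordinate lists; each strand is then cut independently.
# Returns NULL when cut pairs cross (degenerate overlapping-site case) or a
# cut falls outside the sequence.
oracle_digest <- function(seq, enzymes) {
  n <- nchar(seq)
  ct <- cb <- integer(0)
  for (e in enzymes) {
    sites <- oracle_find_sites(seq, e$recognition)
    m <- nchar(e$recognition)
    for (i in seq_len(nrow(sites))) {
      p <- sites$pos[i]
      if (sites$strand[i] == "+") {
        tc <- p + m + e$top_cut; bc <- p + m + e$bottom_cut
      } else {
        tc <- p - e$bottom_cut; bc <- p - e$top_cut
      }
      if (tc < 0L || tc > n || bc < 0L || bc > n) return(NULL)
      ct <- c(ct, tc); cb <- c(cb, bc)
    }
  }
  o <- order(ct, cb)
  ct <- ct[o]; cb <- cb[o]
  dup <- duplicated(paste(ct, cb))
  ct <- ct[!dup]; cb <- cb[!dup]
  if (is.unsorted(cb, strictly = TRUE) && length(cb) > 1L) return(NULL)
  tb <- c(0L, ct, n); bb <- c(0L, cb, n)
  lapply(seq_len(length(ct) + 1L), function(i)
    list(top = substr(seq, tb[i] + 1L, tb[i + 1L]),
         bottom = oracle_revcomp(substr(seq, bb[i] + 1L, bb[i + 1L]))))
}

# a small reference genome with embedded, designable target coordinates
toy_reference <- function(len = 6000L, seed = 101L) {
  setNames(rand_dna(len, seed = seed), "chr1")
}

toy_targets <- function(n = 4L, start0 = 300L, spacing = 1000L,
                        width = 180L, contig = "chr1") {
  data.frame(contig = contig,
             start = start0 + (seq_len(n) - 1L) * spacing,
             end = start0 + (seq_len(n) - 1L) * spacing + width,
             name = sprintf("t%02d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# design a panel over a fresh random reference, retrying seeds until every
# target designs cleanly (random references can drop arms on enzyme sites)
toy_panel <- function(n_targets = 4L, len = 6000L, seed = 101L, ...) {
  ref <- toy_reference(len, seed)
  design_panel(ref, toy_targets(n_targets), ...)
}
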