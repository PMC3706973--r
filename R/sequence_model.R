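#' @importFrom stats median rbinom runif rnorm rpois sd cor quantile setNames lowess aggregate na.omit
#' @importFrom utils write.table read.table head tail
NULL

DNA_RE <- "^[ACGTNacgtn]*$"

check_dna <- function(x, what = "sequence") {
  if (!is.character(x)) stop(what, " must be a character vector", call. = FALSE)
  bad <- !grepl(DNA_RE, x)
  if (any(bad)) {
    stop(what, " contains characters outside {A,C,G,T,N}: ",
         substr(x[bad][1L], 1L, 40L), call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of DNA sequences
#'
#' Vectorised reverse complement over the alphabet \code{A,C,G,T,N}
#' (case preserved).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @examples
#' revcomp("GGATC")  # "GATCC"
#' @export
revcomp <- function(x) {
  check_dna(x)
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1L))
}

#' GC content of DNA sequences
#'
#' Fraction (G + C) / (A + C + G + T); \code{N} bases are excluded from both
#' numerator and denominator.
#'
#' @param x character vector of non-empty DNA sequences.
#' @return numeric vector of fractions in \[0, 1\].
#' @export
gc_content <- function(x) {
  check_dna(x)
  if (any(nchar(x) == 0L)) stop("gc_content: empty sequence", call. = FALSE)
  up <- toupper(x)
  gc <- nchar(gsub("[^GC]", "", up))
  nn <- nchar(gsub("[^N]", "", up))
  denom <- nchar(up) - nn
  ifelse(denom > 0L, gc / denom, NaN)
}

#' Restriction enzyme definition
#'
#' Cut offsets are signed base counts measured 3' of the last recognition base
#' on the strand carrying the recognition sequence. Equal offsets define a
#' blunt cutter.
#'
#' @param name enzyme name.
#' @param recognition recognition sequence (top strand, 5'->3').
#' @param top_cut,bottom_cut cut offsets for the recognition-carrying strand
#'   and its complement.
#' @return an object of class \code{clpp_enzyme}.
#' @export
restriction_enzyme <- function(name, recognition, top_cut, bottom_cut) {
  check_dna(recognition, "recognition")
  if (nchar(recognition) == 0L) stop("empty recognition sequence", call. = FALSE)
  structure(list(name = name, recognition = toupper(recognition),
                 top_cut = as.integer(top_cut),
                 bottom_cut = as.integer(bottom_cut)),
            class = "clpp_enzyme")
}

#' Default enzyme set used for probe trimming
#'
#' MlyI (GAGTC, blunt cut 5 nt downstream on both strands) and BsaI
#' (GGTCTC, cuts 1/5 nt downstream leaving a 4-nt 5' overhang), following
#' standard catalogue geometries; both are overridable wherever enzymes are
#' accepted.
#'
#' @return named list of \code{clpp_enzyme} objects.
#' @export
default_enzymes <- function() {
  list(MlyI = restriction_enzyme("MlyI", "GAGTC", 5L, 5L),
       BsaI = restriction_enzyme("BsaI", "GGTCTC", 1L, 5L))
}

#' Locate restriction sites on both strands
#'
#' Reports every occurrence of the recognition sequence on either strand as a
#' 0-based position of the first recognition base in top-strand coordinates.
#' \code{N} never matches a recognition base.
#'
#' @param seq DNA string.
#' @param enzyme a \code{clpp_enzyme}.
#' @return data.frame with columns \code{pos} (0-based) and \code{strand}
#'   (\code{"+"} or \code{"-"}), sorted by position.
#' @export
find_sites <- function(seq, enzyme) {
  check_dna(seq)
  stopifnot(inherits(enzyme, "clpp_enzyme"))
  subj <- Biostrings::DNAString(toupper(seq))
  hit <- function(pat, strand) {
    m <- Biostrings::matchPattern(pat, subj, fixed = TRUE)
    if (length(m) == 0L) return(NULL)
    data.frame(pos = Biostrings::start(m) - 1L, strand = strand,
               stringsAsFactors = FALSE)
  }
  rc <- revcomp(enzyme$recognition)
  out <- rbind(hit(enzyme$recognition, "+"),
               if (rc != enzyme$recognition) hit(rc, "-"))
  if (is.null(out)) {
    return(data.frame(pos = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

blunt_end <- function(phos = FALSE) {
  list(overhang = "", protruding = "none", phos = phos)
}

#' Construct a DNA duplex
#'
#' A duplex is represented by its top strand (5'->3'), its bottom strand
#' (5'->3', by default the reverse complement of the top), and per-end
#' annotations: the overhang sequence, which strand protrudes as a 5' (or 3')
#' single-stranded extension, and whether the 5' terminus at that end is
#' phosphorylated.
#'
#' @param top top strand sequence.
#' @param bottom bottom strand sequence; default \code{revcomp(top)}.
#' @param left,right end annotation lists (\code{overhang}, \code{protruding},
#'   \code{phos}); default blunt, unphosphorylated.
#' @return an object of class \code{clpp_duplex}.
#' @export
dna_duplex <- function(top, bottom = revcomp(top),
                       left = blunt_end(), right = blunt_end()) {
  check_dna(top, "top strand")
  check_dna(bottom, "bottom strand")
  structure(list(top = toupper(top), bottom = toupper(bottom),
                 left = left, right = right),
            class = "clpp_duplex")
}

#' @export
print.clpp_duplex <- function(x, ...) {
  show <- function(s) if (nchar(s) > 60L)
    paste0(substr(s, 1, 28), "...", substr(s, nchar(s) - 27, nchar(s))) else s
  cat("cLPP duplex: top ", nchar(x$top), " nt / bottom ", nchar(x$bottom),
      " nt\n  top    5'-", show(x$top), "-3'\n", sep = "")
  for (side in c("left", "right")) {
    e <- x[[side]]
    cat("  ", side, ": ",
        if (e$protruding == "none") "blunt"
        else paste0(e$protruding, "-strand 5' overhang ", e$overhang),
        if (isTRUE(e$phos)) " [5'-P]" else "", "\n", sep = "")
  }
  invisible(x)
}

duplex_length <- function(x) max(nchar(x$top), nchar(x$bottom))

#' Digest a duplex with one or more restriction enzymes
#'
#' Applies every cut of every enzyme at its catalogue offset and returns the
#' fragments 5'->3' along the top strand. Junction overhangs are annotated on
#' both flanking fragments, and every newly created 5' end is flagged as
#' phosphorylated (enzymatic cleavage leaves 5'-phosphates). Cuts whose
#' position would fall outside the sequence (site too close to an end) are
#' skipped and recorded in the \code{"skipped_sites"} attribute.
#'
#' @param duplex a \code{clpp_duplex}.
#' @param enzymes list of \code{clpp_enzyme} objects.
#' @return list of \code{clpp_duplex} fragments (the input, unchanged, when no
#'   site is found), with attribute \code{skipped_sites}.
#' @export
digest <- function(duplex, enzymes) {
  stopifnot(inherits(duplex, "clpp_duplex"))
  if (inherits(enzymes, "clpp_enzyme")) enzymes <- list(enzymes)
  seq <- duplex$top
  n <- nchar(seq)
  cuts <- matrix(integer(0), ncol = 2L)
  skipped <- list()
  for (enz in enzymes) {
    sites <- find_sites(seq, enz)
    m <- nchar(enz$recognition)
    for (i in seq_len(nrow(sites))) {
      p <- sites$pos[i]
      if (sites$strand[i] == "+") {
        ct <- p + m + enz$top_cut
        cb <- p + m + enz$bottom_cut
      } else {
        ct <- p - enz$bottom_cut
        cb <- p - enz$top_cut
      }
      if (ct < 0L || ct > n || cb < 0L || cb > n) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(enzyme = enz$name, pos = p, strand = sites$strand[i])
        next
      }
      cuts <- rbind(cuts, c(ct, cb))
    }
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(enzyme = character(0), pos = integer(0), strand = character(0))
  if (nrow(skipped)) {
    warning("digest: ", nrow(skipped), " cut(s) outside sequence skipped",
            call. = FALSE)
  }
  if (nrow(cuts) == 0L) {
    out <- list(duplex)
    attr(out, "skipped_sites") <- skipped
    return(out)
  }
  cuts <- unique(cuts[order(cuts[, 1L], cuts[, 2L]), , drop = FALSE])
  # drop cuts that would cross a previously accepted cut on either strand
  keep <- rep(TRUE, nrow(cuts))
  last_cb <- -Inf
  for (i in seq_len(nrow(cuts))) {
    if (cuts[i, 2L] <= last_cb) keep[i] <- FALSE else last_cb <- cuts[i, 2L]
  }
  cuts <- cuts[keep, , drop = FALSE]
  tb <- c(0L, cuts[, 1L], n)
  bb <- c(0L, cuts[, 2L], n)
  frags <- vector("list", nrow(cuts) + 1L)
  for (i in seq_along(frags)) {
    top_i <- substr(seq, tb[i] + 1L, tb[i + 1L])
    bot_i <- revcomp(substr(seq, bb[i] + 1L, bb[i + 1L]))
    left <- if (i == 1L) duplex$left else
      junction_end(seq, cuts[i - 1L, 1L], cuts[i - 1L, 2L], side = "right_frag")
    right <- if (i == length(frags)) duplex$right else
      junction_end(seq, cuts[i, 1L], cuts[i, 2L], side = "left_frag")
    frags[[i]] <- dna_duplex(top_i, bot_i, left = left, right = right)
  }
  attr(frags, "skipped_sites") <- skipped
  frags
}

# End annotation at a cut with top cut `ct` and bottom cut `cb` (top coords).
# ct < cb: complementary 5' overhangs over seq[ct:cb] -- the top strand
# protrudes on the right-hand fragment's left end, the bottom strand on the
# left-hand fragment's right end. ct > cb mirrors this (3'-protruding ends).
# The overhang is reported as the top-strand sequence of the junction window
# on both fragments; `protruding` records which strand is single-stranded.
junction_end <- function(seq, ct, cb, side) {
  d <- cb - ct
  if (d == 0L) return(blunt_end(phos = TRUE))
  oh <- if (d > 0L) substr(seq, ct + 1L, cb) else substr(seq, cb + 1L, ct)
  prot <- if ((d > 0L) == (side == "right_frag")) "top" else "bottom"
  list(overhang = oh, protruding = prot, phos = TRUE)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a named character vector of sequences to FASTA (60-column wrap)
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

# run code under a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
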