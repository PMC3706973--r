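#' Default adaptor and linker set
#'
#' Flow-cell adaptors (P5/P7), the two post-capture amplification sites
#' (linkers) embedded in the probe backbone, the default 6-base sample index
#' (P7 side), and the read 1 / read 2 sequencing primers.
#'
#' @return named list of sequences.
#' @export
default_adaptors <- function() {
  list(P5 = "AATGATACGGCGACCACCGAGATCTACAC",
       P7 = "CAAGCAGAAGACGGCATACGAGAT",
       linker_F = "GATCTTAACCCTCACTAAAGGGAGGC",
       linker_R = "GATCCCAATTTAGGTGACACTATAGGCGG",
       index = "ACGTAC",
       read1_primer = "GATCTTAACCCTCACTAAAGGGAGGCGCGCC",
       read2_primer = "GATCCCAATTTAGGTGACACTATAGGCGGCCGC")
}

mutate_seq <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  vapply(seq, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < error_rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Reciprocal paired-end library amplification
#'
#' Amplifies every captured circle in two separate PCRs during which the
#' adaptors swap positions at the template ends: in PCR-A read 1 reads the
#' sense insert strand and read 2 the antisense strand; in PCR-B the
#' orientations are reversed. Pooling both PCRs therefore yields four distinct
#' read species per original template (two in standard single-PCR mode).
#'
#' @param circles data.frame of captures (needs \code{capture_id},
#'   \code{arm_up}, \code{insert}, \code{arm_down}; arms may be empty
#'   strings).
#' @param adaptors adaptor set, see \code{\link{default_adaptors}}.
#' @param mode \code{"rpe"} (PCR-A + PCR-B pooled) or \code{"standard"}
#'   (PCR-A only).
#' @param index 6-base sample index attached P7-side.
#' @param error_rate per-base substitution rate applied independently per PCR
#'   to each template interior (PCR amplification errors).
#' @param seed seed for the error process.
#' @return data.frame of templates: \code{template_id, capture_id, pcr,
#'   interior} (the template between the amplification sites, oriented so
#'   that read 1 reads it 5'->3'), \code{seq3} (adaptor continuation past the
#'   interior for read 1), \code{seq5rc} (continuation for read 2),
#'   \code{index}.
#' @export
amplify_rpe <- function(circles, adaptors = default_adaptors(),
                        mode = c("rpe", "standard"),
                        index = adaptors$index, error_rate = 0, seed = 1L) {
  mode <- match.arg(mode)
  if (!nrow(circles)) stop("no captured circles", call. = FALSE)
  core <- paste0(circles$arm_up, circles$insert, circles$arm_down)
  pcrs <- if (mode == "rpe") c("A", "B") else "A"
  with_seed(seed, {
    out <- lapply(pcrs, function(pcr) {
      interior <- mutate_seq(if (pcr == "A") core else revcomp(core),
                             error_rate)
      linker5 <- if (pcr == "A") adaptors$linker_F else adaptors$linker_R
      linker3 <- if (pcr == "A") adaptors$linker_R else adaptors$linker_F
      data.frame(
        template_id = paste0(circles$capture_id, "_", pcr),
        capture_id = circles$capture_id, pcr = pcr, interior = interior,
        seq3 = paste0(revcomp(linker3), revcomp(index), revcomp(adaptors$P7)),
        seq5rc = paste0(revcomp(linker5), revcomp(adaptors$P5)),
        index = index, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

phred_string <- function(q) {
  rawToChar(as.raw(pmin(pmax(q, 0L), 41L) + 33L))
}

quality_profile <- function(len, q0, slope, floor = 2L) {
  as.integer(round(pmax(floor, q0 - slope * (seq_len(len) - 1L))))
}

#' Generate paired-end reads from library templates
#'
#' Mate 1 reads each template interior from the read-1 amplification-site
#' junction inward (continuing into the far adaptor when the read is longer
#' than the interior); mate 2 reads from the opposite junction on the other
#' strand. Phred qualities start at \code{q0} and decay linearly, with mate 2
#' decaying \code{q2_factor} times faster than mate 1. Reads carry the sample
#' index in their name (\code{idx=} field) and, unless \code{blind}, a
#' parseable ground-truth suffix (capture id and PCR label).
#'
#' @param templates data.frame from \code{\link{amplify_rpe}}.
#' @param r1_len,r2_len read lengths (bases).
#' @param depth duplication multiplier; values > 1 resample templates with
#'   replacement (PCR duplicates).
#' @param q0 starting Phred quality.
#' @param q_slope per-base mate-1 quality decay.
#' @param q2_factor mate-2 decay relative to mate 1.
#' @param seed seed for resampling.
#' @param blind drop the ground-truth suffix from read names.
#' @return list with \code{r1} and \code{r2}
#'   (\code{QualityScaledDNAStringSet}).
#' @export
generate_reads <- function(templates, r1_len = 175L, r2_len = 150L,
                           depth = 1L, q0 = 38L, q_slope = 0.045,
                           q2_factor = 1.5, seed = 1L, blind = FALSE) {
  stopifnot(r1_len > 0L, r2_len > 0L)
  idx <- seq_len(nrow(templates))
  if (depth > 1L)
    idx <- with_seed(seed, sample(idx, nrow(templates) * depth,
                                  replace = TRUE))
  tp <- templates[idx, , drop = FALSE]
  fwd <- paste0(tp$interior, tp$seq3)
  rev <- paste0(revcomp(tp$interior), tp$seq5rc)
  s1 <- substr(fwd, 1L, r1_len)
  s2 <- substr(rev, 1L, r2_len)
  ids <- if (blind) {
    sprintf("rd%06d:idx=%s", seq_along(idx), tp$index)
  } else {
    sprintf("rd%06d:%s:%s:idx=%s", seq_along(idx), tp$capture_id, tp$pcr,
            tp$index)
  }
  make_set <- function(seqs, len, slope) {
    qs <- vapply(nchar(seqs), function(n)
      phred_string(quality_profile(n, q0, slope)), "")
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::QualityScaledDNAStringSet(x, Biostrings::PhredQuality(qs))
  }
  list(r1 = make_set(s1, r1_len, q_slope),
       r2 = make_set(s2, r2_len, q_slope * q2_factor))
}

#' Write a quality-scaled read set to FASTQ
#' @param reads a \code{QualityScaledDNAStringSet}.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}

#' Read a FASTQ file as a quality-scaled read set
#' @param path FASTQ file.
#' @return \code{QualityScaledDNAStringSet}.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropped metadata columns when rebuilding the
  # quality-scaled set; nothing is lost for plain FASTQ records
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Distinct read species per original template
#'
#' Counts the distinct (mate, insert-strand) combinations the pooled library
#' produces for each capture.
#'
#' @param templates data.frame from \code{\link{amplify_rpe}}.
#' @return data.frame \code{capture_id, n_species}.
#' @export
read_species_count <- function(templates) {
  species <- unique(data.frame(
    capture_id = rep(templates$capture_id, 2L),
    mate = rep(1:2, each = nrow(templates)),
    insert_strand = c(ifelse(templates$pcr == "A", "sense", "antisense"),
                      ifelse(templates$pcr == "A", "antisense", "sense")),
    stringsAsFactors = FALSE))
  agg <- aggregate(species$mate, by = list(capture_id = species$capture_id),
                   FUN = length)
  data.frame(capture_id = agg$capture_id, n_species = agg$x,
             stringsAsFactors = FALSE)
}

#' Insert coverage attainable from pooled rPE reads
#'
#' For a template interior of length \code{insert_len}, generates the pooled
#' read pairs from a random insert, maps every read sequence back onto the
#' insert by exact string matching (longest matching read prefix, either
#' strand), and reports whether the union of the matched intervals covers
#' every insert base.
#'
#' @param insert_len interior length in bases.
#' @param r1_len,r2_len read lengths.
#' @param mode \code{"rpe"} or \code{"standard"}.
#' @param seed seed for the random insert sequence.
#' @return logical: fully covered.
#' @export
insert_fully_covered <- function(insert_len, r1_len = 175L, r2_len = 150L,
                                 mode = c("rpe", "standard"), seed = 7L) {
  mode <- match.arg(mode)
  ins <- with_seed(seed + insert_len, random_dna(insert_len))
  circ <- data.frame(capture_id = "c1", arm_up = "", arm_down = "",
                     insert = ins, stringsAsFactors = FALSE)
  tp <- amplify_rpe(circ, mode = mode)
  rd <- generate_reads(tp, r1_len = r1_len, r2_len = r2_len)
  ins_rc <- revcomp(ins)
  cov <- logical(insert_len)
  for (r in c(as.character(rd$r1), as.character(rd$r2))) {
    for (k in seq(min(nchar(r), insert_len), 20L, by = -1L)) {
      pre <- substr(r, 1L, k)
      j <- regexpr(pre, ins, fixed = TRUE)
      if (j > 0L) { cov[j:(j + k - 1L)] <- TRUE; break }
      j <- regexpr(pre, ins_rc, fixed = TRUE)
      if (j > 0L) {
        lo <- insert_len - (j + k - 1L) + 1L
        cov[lo:(lo + k - 1L)] <- TRUE
        break
      }
    }
  }
  all(cov)
}

#' Largest fully covered insert length under a read-length configuration
#'
#' Sweeps interior lengths and returns the largest one at which every base is
#' covered by at least one pooled read.
#'
#' @param lengths integer vector of interior lengths to sweep.
#' @param r1_len,r2_len read lengths.
#' @param mode \code{"rpe"} or \code{"standard"}.
#' @return largest fully covered length (or \code{NA} if none).
#' @export
max_covered_insert <- function(lengths = 300:400, r1_len = 175L,
                               r2_len = 150L, mode = c("rpe", "standard")) {
  mode <- match.arg(mode)
  ok <- vapply(lengths, insert_fully_covered, logical(1L),
               r1_len = r1_len, r2_len = r2_len, mode = mode)
  if (!any(ok)) return(NA_integer_)
  max(lengths[ok])
}
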