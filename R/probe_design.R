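#' Packaged synthetic spacer backbone
#'
#' A synthetic 280 bp spacer backbone free of MlyI and BsaI recognition sites
#' on either strand, with the two post-capture amplification-primer landing
#' sites embedded at its ends. It stands in for the bacteriophage-lambda
#' spacer of the original wet-lab protocol.
#'
#' @return single DNA string (280 bases).
#' @export
default_backbone <- function() {
  path <- system.file("extdata", "backbone_synthetic.fa", package = "clppkit",
                      mustWork = TRUE)
  unname(read_fasta(path)[1L])
}

#' Construct a genomic interval (0-based, half-open)
#' @param contig contig name.
#' @param start,end 0-based half-open coordinates.
#' @param name optional label.
#' @return list of class \code{clpp_interval}.
#' @export
genomic_interval <- function(contig, start, end, name = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid interval: need 0 <= start < end", call. = FALSE)
  if (is.null(name)) name <- sprintf("%s:%d-%d", contig, start, end)
  structure(list(contig = contig, start = start, end = end, name = name),
            class = "clpp_interval")
}

interval_length <- function(iv) iv$end - iv$start

arm_has_site <- function(arm, enzymes) {
  any(vapply(enzymes, function(e) nrow(find_sites(arm, e)) > 0L, logical(1L)))
}

#' Select capture arms flanking a target
#'
#' Arms are exact reference slices immediately flanking the gap-fill region:
#' \code{[start - arm_len, start)} upstream and \code{[end, end + arm_len)}
#' downstream. If either arm contains an internal MlyI/BsaI site, a single
#' greedy pass varies the arm length by up to 3 bases (within 18--28) to
#' dodge it.
#'
#' @param reference named character vector of contig sequences.
#' @param target a \code{clpp_interval} (the gap-fill region).
#' @param arm_len requested arm length in bases (18--28).
#' @param enzymes enzymes whose sites must not occur inside an arm.
#' @return list with \code{status} (\code{"ok"}, \code{"edge_too_close"} or
#'   \code{"arm_has_site"}); on success also \code{arm_up}, \code{arm_down},
#'   their intervals and the arm lengths used.
#' @export
select_arms <- function(reference, target, arm_len = 25L,
                        enzymes = default_enzymes()) {
  arm_len <- as.integer(arm_len)
  if (arm_len < 18L || arm_len > 28L)
    stop("arm_len must be within [18, 28]", call. = FALSE)
  ctg <- reference[[target$contig]]
  if (is.null(ctg)) stop("unknown contig: ", target$contig, call. = FALSE)
  n <- nchar(ctg)
  if (target$end > n) stop("target beyond contig end", call. = FALSE)
  fail <- function(status) list(status = status, target = target$name)
  try_len <- function(len_up, len_down) {
    if (target$start - len_up < 0L || target$end + len_down > n) return(NULL)
    up <- substr(ctg, target$start - len_up + 1L, target$start)
    dn <- substr(ctg, target$end + 1L, target$end + len_down)
    if (arm_has_site(up, enzymes) || arm_has_site(dn, enzymes)) return(NULL)
    list(status = "ok", target = target$name,
         arm_up = up, arm_down = dn,
         arm_up_iv = genomic_interval(target$contig, target$start - len_up,
                                      target$start),
         arm_down_iv = genomic_interval(target$contig, target$end,
                                        target$end + len_down),
         arm_up_len = len_up, arm_down_len = len_down)
  }
  if (target$start - arm_len < 0L || target$end + arm_len > n)
    return(fail("edge_too_close"))
  cand <- unique(pmin(28L, pmax(18L, arm_len + c(0L, 1L, -1L, 2L, -2L, 3L, -3L))))
  for (lu in cand) for (ld in cand) {
    res <- try_len(lu, ld)
    if (!is.null(res)) return(res)
  }
  fail("arm_has_site")
}

#' Build the precursor PCR product and its primers for one design
#'
#' The forward primer carries the MlyI site plus a 5-base spacer, the upstream
#' arm, and the backbone's 5' annealing region; the reverse primer carries the
#' BsaI site plus a 1-base spacer, the reverse-complemented downstream arm and
#' the reverse-complemented 3' annealing region (extended so that a 25-base
#' arm yields a 60-mer). The spacers place the MlyI blunt cut exactly at the
#' upstream arm boundary and the BsaI 4-base 5' overhang inside the downstream
#' arm, so that digestion leaves only target sequence at each probe end.
#'
#' @param arms result of \code{\link{select_arms}} with status \code{"ok"}.
#' @param backbone spacer backbone sequence (site-free).
#' @param enzymes list with elements \code{MlyI} and \code{BsaI}.
#' @param anneal_len forward-primer backbone annealing length.
#' @param rev_anneal_len reverse-primer backbone annealing length.
#' @return list with \code{forward_primer}, \code{reverse_primer} and
#'   \code{precursor} (a \code{clpp_duplex}).
#' @export
build_precursor <- function(arms, backbone, enzymes = default_enzymes(),
                            anneal_len = 25L, rev_anneal_len = 28L) {
  stopifnot(identical(arms$status, "ok"))
  check_dna(backbone, "backbone")
  if (nchar(backbone) < 2L * anneal_len)
    stop("backbone shorter than twice the annealing length", call. = FALSE)
  for (e in enzymes) {
    if (nrow(find_sites(backbone, e)) > 0L)
      stop("backbone contains a ", e$name, " site", call. = FALSE)
  }
  spacer_f <- "CACAC"   # 5 nt: MlyI cuts 5 nt past the site, at the arm start
  spacer_r <- "T"       # 1 nt: BsaI top cut 1 nt past the site
  mly <- enzymes$MlyI$recognition
  bsa_rc <- revcomp(enzymes$BsaI$recognition)
  top <- paste0(mly, spacer_f, arms$arm_up, backbone,
                arms$arm_down, spacer_r, bsa_rc)
  fwd <- paste0(mly, spacer_f, arms$arm_up, substr(backbone, 1L, anneal_len))
  nb <- nchar(backbone)
  rev_tail_len <- nchar(bsa_rc) + nchar(spacer_r) + arms$arm_down_len +
    rev_anneal_len
  rev <- revcomp(substr(top, nchar(top) - rev_tail_len + 1L, nchar(top)))
  for (e in enzymes) {
    if (nrow(find_sites(top, e)) != 1L)
      stop("precursor for ", arms$target, " does not contain exactly one ",
           e$name, " site", call. = FALSE)
  }
  list(forward_primer = fwd, reverse_primer = rev,
       precursor = dna_duplex(top))
}

#' Release the functional probe duplex from a precursor
#'
#' Digests the precursor with MlyI and BsaI, discards the outer fragments and
#' returns the middle fragment -- the functional cLPP duplex, i.e. two
#' complementary single-stranded padlock probes, each capable of capturing one
#' strand of the genomic target. Both newly cut 5' ends carry phosphates. Each
#' strand's termini are validated against the capture arms.
#'
#' @param precursor a \code{clpp_duplex} with exactly one site per enzyme.
#' @param arms the arm pair the precursor was built from.
#' @param enzymes list with elements \code{MlyI} and \code{BsaI}.
#' @return a \code{clpp_duplex} functional probe.
#' @export
make_functional_probe <- function(precursor, arms,
                                  enzymes = default_enzymes()) {
  for (e in enzymes) {
    if (nrow(find_sites(precursor$top, e)) != 1L)
      stop("precursor must contain exactly one ", e$name, " site",
           call. = FALSE)
  }
  frags <- digest(precursor, enzymes)
  if (length(frags) != 3L)
    stop("digestion of precursor for ", arms$target,
         " did not yield three fragments", call. = FALSE)
  probe <- frags[[2L]]
  up <- arms$arm_up; dn <- arms$arm_down
  ok <- startsWith(probe$top, up) &&
    endsWith(probe$top, substr(dn, 1L, nchar(dn) - 4L)) &&
    startsWith(probe$bottom, revcomp(dn)) &&
    endsWith(probe$bottom, revcomp(up))
  if (!ok)
    stop("functional probe termini do not equal the arms for design ",
         arms$target, call. = FALSE)
  probe
}

#' Tile an oversize target into overlapping sub-targets
#'
#' Targets no longer than \code{max_gap} are returned unchanged; larger
#' targets are split into the minimum number of sub-targets of at most
#' \code{max_gap} bases with the configured overlap, jointly covering the
#' target.
#'
#' @param target a \code{clpp_interval}.
#' @param max_gap maximum gap-fill length per probe (bases).
#' @param overlap overlap between adjacent sub-targets (bases).
#' @return list of \code{clpp_interval}.
#' @export
tile_target <- function(target, max_gap = 550L, overlap = 50L) {
  max_gap <- as.integer(max_gap); overlap <- as.integer(overlap)
  if (!(max_gap > overlap && overlap >= 0L))
    stop("need max_gap > overlap >= 0", call. = FALSE)
  len <- interval_length(target)
  if (len <= max_gap) return(list(target))
  n <- ceiling((len - overlap) / (max_gap - overlap))
  sub_len <- ceiling((len + (n - 1L) * overlap) / n)
  step <- sub_len - overlap
  lapply(seq_len(n), function(i) {
    s <- target$start + (i - 1L) * step
    e <- min(s + sub_len, target$end)
    if (i == n) e <- target$end
    genomic_interval(target$contig, s, e, sprintf("%s.%d", target$name, i))
  })
}

#' Abundance weights from target GC content
#'
#' Probe amounts are up-weighted for GC-rich targets: weight 1 at or below
#' \code{gc_threshold}, then a linear ramp reaching \code{weight_max} at
#' \code{gc_max} (capped beyond).
#'
#' @param gc numeric vector of GC fractions (captured region: arms + insert).
#' @param gc_threshold GC fraction at which up-weighting starts.
#' @param gc_max GC fraction at which the ramp reaches \code{weight_max}.
#' @param weight_max maximum abundance weight.
#' @return numeric vector of weights >= 1.
#' @export
assign_weights <- function(gc, gc_threshold = 0.65, gc_max = 0.80,
                           weight_max = 4) {
  stopifnot(gc_max > gc_threshold, weight_max >= 1)
  ifelse(gc <= gc_threshold, 1,
         pmin(weight_max,
              1 + (weight_max - 1) * (gc - gc_threshold) /
                (gc_max - gc_threshold)))
}

#' Build panel reference files from a list of designs
#'
#' Emits one amplicon record (amplification-site flank + upstream arm + insert
#' + downstream arm + flank) and one insert-only record per design, plus a BED
#' table of the genomic targets, all ordered by genomic coordinate.
#'
#' @param designs list of design records from \code{\link{design_panel}}.
#' @param linker_f,linker_r post-capture amplification sites flanking the
#'   amplicon (defaults from \code{\link{default_adaptors}}).
#' @return object of class \code{clpp_panel_refs} with elements
#'   \code{amplicons}, \code{inserts}, \code{targets} (BED data.frame),
#'   \code{insert_offset} and \code{meta}.
#' @export
build_references <- function(designs,
                             linker_f = default_adaptors()$linker_F,
                             linker_r = default_adaptors()$linker_R) {
  if (!length(designs)) {
    return(structure(list(amplicons = character(0), inserts = character(0),
                          targets = data.frame(contig = character(0),
                                               start = integer(0),
                                               end = integer(0),
                                               name = character(0)),
                          insert_offset = integer(0),
                          meta = data.frame(), designs = list()),
                     class = "clpp_panel_refs"))
  }
  ids <- vapply(designs, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate design names", call. = FALSE)
  ord <- order(vapply(designs, `[[`, "", "contig"),
               vapply(designs, function(d) d$start, integer(1L)))
  designs <- designs[ord]; ids <- ids[ord]
  flank_r <- revcomp(linker_r)
  amplicons <- vapply(designs, function(d)
    paste0(linker_f, d$arm_up, d$insert_seq, d$arm_down, flank_r), "")
  inserts <- vapply(designs, `[[`, "", "insert_seq")
  names(amplicons) <- names(inserts) <- ids
  targets <- data.frame(
    contig = vapply(designs, `[[`, "", "contig"),
    start = vapply(designs, function(d) d$start, integer(1L)),
    end = vapply(designs, function(d) d$end, integer(1L)),
    name = ids, stringsAsFactors = FALSE)
  meta <- data.frame(
    id = ids,
    arm_up_len = vapply(designs, function(d) nchar(d$arm_up), integer(1L)),
    arm_down_len = vapply(designs, function(d) nchar(d$arm_down), integer(1L)),
    flank_f_len = nchar(linker_f), flank_r_len = nchar(flank_r),
    insert_len = nchar(inserts), amplicon_len = nchar(amplicons),
    gc = vapply(designs, function(d) d$gc, numeric(1L)),
    weight = vapply(designs, function(d) d$weight, numeric(1L)),
    stringsAsFactors = FALSE)
  structure(list(amplicons = amplicons, inserts = inserts, targets = targets,
                 insert_offset = setNames(nchar(linker_f) + meta$arm_up_len,
                                          ids),
                 meta = meta, designs = designs),
            class = "clpp_panel_refs")
}

#' Load panel references from a directory written by \code{\link{write_panel}}
#'
#' Rebuilds the reference object needed by the processing functions from
#' \code{amplicons.fa}, \code{inserts.fa} and \code{targets.bed}. The insert
#' offset within each amplicon is recovered by locating the insert sequence.
#'
#' @param dir panel directory.
#' @return a \code{clpp_panel_refs}.
#' @export
read_panel <- function(dir) {
  amplicons <- read_fasta(file.path(dir, "amplicons.fa"))
  inserts <- read_fasta(file.path(dir, "inserts.fa"))
  bed <- read.table(file.path(dir, "targets.bed"), sep = "\t",
                    stringsAsFactors = FALSE)
  targets <- data.frame(contig = bed$V1, start = as.integer(bed$V2),
                        end = as.integer(bed$V3), name = bed$V4,
                        stringsAsFactors = FALSE)
  off <- vapply(names(amplicons), function(a)
    as.integer(regexpr(inserts[[a]], amplicons[[a]], fixed = TRUE)) - 1L,
    integer(1L))
  if (any(off < 0L)) stop("insert not found within its amplicon", call. = FALSE)
  structure(list(amplicons = amplicons, inserts = inserts, targets = targets,
                 insert_offset = off,
                 meta = data.frame(id = names(amplicons),
                                   insert_len = nchar(inserts),
                                   amplicon_len = nchar(amplicons),
                                   stringsAsFactors = FALSE),
                 designs = list()),
            class = "clpp_panel_refs")
}

#' Design a cLPP panel for a set of targets
#'
#' Runs the full designer: oversize targets are tiled, arms selected,
#' precursor primers and functional probe duplexes built, GC-based abundance
#' weights assigned, and the amplicon / insert-only references emitted.
#' Targets that cannot be designed (contig edge, undodgeable internal
#' restriction site, precursor site-count violation) are reported and skipped.
#'
#' @param reference named character vector of contig sequences.
#' @param targets data.frame with columns \code{contig,start,end} and
#'   optionally \code{name} (BED convention, 0-based half-open).
#' @param backbone spacer backbone; default the packaged 280 bp synthetic one.
#' @param arm_len requested arm length (18--28).
#' @param max_gap maximum gap-fill length; larger targets are tiled.
#' @param overlap tiling overlap in bases.
#' @param enzymes trimming enzymes.
#' @param snv_mask optional data.frame of intervals (\code{contig,start,end})
#'   of known variants; arms overlapping the mask are flagged with a warning
#'   in the report but kept.
#' @param gc_threshold,gc_max,weight_max abundance-weight policy, see
#'   \code{\link{assign_weights}}.
#' @return object of class \code{clpp_panel}: \code{designs},
#'   \code{references} (\code{clpp_panel_refs}), \code{report} (one row per
#'   attempted sub-target) and \code{params}.
#' @export
design_panel <- function(reference, targets, backbone = default_backbone(),
                         arm_len = 25L, max_gap = 550L, overlap = 50L,
                         enzymes = default_enzymes(), snv_mask = NULL,
                         gc_threshold = 0.65, gc_max = 0.80, weight_max = 4) {
  if (!nrow(targets)) {
    refs <- build_references(list())
    return(structure(list(designs = list(), references = refs,
                          report = data.frame(), params = list()),
                     class = "clpp_panel"))
  }
  if (is.null(targets$name))
    targets$name <- sprintf("%s:%d-%d", targets$contig, targets$start,
                            targets$end)
  subs <- list()
  for (i in seq_len(nrow(targets))) {
    iv <- genomic_interval(targets$contig[i], targets$start[i],
                           targets$end[i], targets$name[i])
    subs <- c(subs, tile_target(iv, max_gap, overlap))
  }
  designs <- list(); rows <- list()
  for (iv in subs) {
    row <- data.frame(id = iv$name, contig = iv$contig, start = iv$start,
                      end = iv$end, gap_len = interval_length(iv),
                      status = NA_character_, gc = NA_real_,
                      weight = NA_real_, note = "", stringsAsFactors = FALSE)
    arms <- select_arms(reference, iv, arm_len, enzymes)
    if (arms$status != "ok") {
      row$status <- arms$status
      rows[[length(rows) + 1L]] <- row
      next
    }
    pre <- tryCatch(build_precursor(arms, backbone, enzymes),
                    error = function(e) conditionMessage(e))
    if (is.character(pre)) {
      row$status <- "precursor_failed"; row$note <- pre
      rows[[length(rows) + 1L]] <- row
      next
    }
    probe <- make_functional_probe(pre$precursor, arms, enzymes)
    insert_seq <- substr(reference[[iv$contig]], iv$start + 1L, iv$end)
    gc <- gc_content(paste0(arms$arm_up, insert_seq, arms$arm_down))
    if (!is.null(snv_mask)) {
      hit <- any(snv_mask$contig == iv$contig &
                   snv_mask$end > arms$arm_up_iv$start &
                   snv_mask$start < arms$arm_down_iv$end &
                   (snv_mask$start < iv$start | snv_mask$end > iv$end))
      if (hit) row$note <- "arm overlaps masked SNV"
    }
    d <- list(id = iv$name, contig = iv$contig, start = iv$start,
              end = iv$end, arm_up = arms$arm_up, arm_down = arms$arm_down,
              arm_up_iv = arms$arm_up_iv, arm_down_iv = arms$arm_down_iv,
              forward_primer = pre$forward_primer,
              reverse_primer = pre$reverse_primer,
              precursor = pre$precursor, functional_probe = probe,
              insert_seq = insert_seq, gc = gc, weight = NA_real_)
    row$status <- "ok"; row$gc <- gc
    designs[[length(designs) + 1L]] <- d
    rows[[length(rows) + 1L]] <- row
  }
  report <- do.call(rbind, rows)
  if (length(designs)) {
    w <- assign_weights(vapply(designs, `[[`, 0, "gc"),
                        gc_threshold, gc_max, weight_max)
    for (i in seq_along(designs)) designs[[i]]$weight <- w[i]
    report$weight[report$status == "ok"] <- w
  }
  refs <- build_references(designs)
  structure(list(designs = refs$designs, references = refs, report = report,
                 params = list(arm_len = arm_len, max_gap = max_gap,
                               overlap = overlap, backbone = backbone,
                               gc_threshold = gc_threshold, gc_max = gc_max,
                               weight_max = weight_max)),
            class = "clpp_panel")
}

#' @export
print.clpp_panel <- function(x, ...) {
  ok <- sum(x$report$status == "ok")
  cat("cLPP panel:", ok, "designs from", nrow(x$report),
      "sub-targets (", nrow(x$report) - ok, "failed )\n")
  invisible(x)
}

#' Write panel files to a directory
#'
#' Writes \code{primers.tsv}, \code{probes.fa}, \code{amplicons.fa},
#' \code{inserts.fa}, \code{targets.bed} and \code{design_report.tsv}.
#'
#' @param panel a \code{clpp_panel}.
#' @param dir output directory (created if needed).
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refs <- panel$references
  write_fasta(refs$amplicons, file.path(dir, "amplicons.fa"))
  write_fasta(refs$inserts, file.path(dir, "inserts.fa"))
  probes <- unlist(lapply(panel$designs, function(d)
    setNames(list(d$functional_probe$top, d$functional_probe$bottom),
             paste0(d$id, c("_top", "_bottom")))))
  if (length(probes)) write_fasta(probes, file.path(dir, "probes.fa"))
  primers <- data.frame(
    id = vapply(panel$designs, `[[`, "", "id"),
    forward = vapply(panel$designs, `[[`, "", "forward_primer"),
    reverse = vapply(panel$designs, `[[`, "", "reverse_primer"),
    stringsAsFactors = FALSE)
  write.table(primers, file.path(dir, "primers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(refs$targets, file.path(dir, "targets.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(panel$report, file.path(dir, "design_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
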