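# Karlin-Altschul-style E-value for ungapped blastn-like scoring
# (match +1 / mismatch -2): E = K * m * n * exp(-lambda * S)
KA_LAMBDA <- 1.28
KA_K <- 0.46

evalue_from_score <- function(score, m, n_db) {
  KA_K * m * n_db * exp(-KA_LAMBDA * score)
}

hamming <- function(a, b) {
  mapply(function(x, y) sum(strsplit(x, "")[[1L]] != strsplit(y, "")[[1L]]),
         a, b, USE.NAMES = FALSE)
}

index_from_names <- function(nms) {
  out <- sub(".*idx=([ACGTN]+).*", "\\1", nms)
  out[out == nms] <- NA_character_
  out
}

#' Demultiplex read pairs by sample index
#'
#' Assigns each read pair to the unique sample whose 6-base index matches the
#' read's index within \code{max_mismatch} substitutions; ambiguous or
#' non-matching pairs go to the \code{"undetermined"} bin.
#'
#' @param reads list with \code{r1}, \code{r2}
#'   (\code{QualityScaledDNAStringSet}; read names carry an \code{idx=}
#'   field).
#' @param index_table data.frame with columns \code{sample} and \code{index}
#'   (all indexes the same length).
#' @param max_mismatch maximum Hamming distance for a match.
#' @return named list of per-sample read lists (\code{r1}, \code{r2}),
#'   including \code{undetermined}.
#' @export
demultiplex <- function(reads, index_table, max_mismatch = 0L) {
  if (anyDuplicated(index_table$index))
    stop("duplicate index in sample table", call. = FALSE)
  if (length(unique(nchar(index_table$index))) != 1L)
    stop("all sample indexes must have the same length", call. = FALSE)
  obs <- index_from_names(names(reads$r1))
  uobs <- unique(obs)
  assign_one <- function(ix) {
    if (is.na(ix) || nchar(ix) != nchar(index_table$index[1L]))
      return("undetermined")
    d <- hamming(rep(ix, nrow(index_table)), index_table$index)
    hit <- which(d <= max_mismatch)
    if (length(hit) == 1L) index_table$sample[hit] else "undetermined"
  }
  lut <- vapply(uobs, assign_one, "")
  dest <- lut[match(obs, uobs)]
  out <- lapply(c(index_table$sample, "undetermined"), function(s) {
    sel <- which(dest == s)
    list(r1 = reads$r1[sel], r2 = reads$r2[sel])
  })
  names(out) <- c(index_table$sample, "undetermined")
  out
}

# k-mer index over a reference set, both strands
kmer_index <- function(seqs, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (nm in names(seqs)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqs[[nm]] else revcomp(seqs[[nm]])
      n <- nchar(s) - k + 1L
      if (n < 1L) next
      kms <- unique(substring(s, seq_len(n), seq_len(n) + k - 1L))
      tag <- paste0(nm, "\t", strand)
      for (km in kms) env[[km]] <- c(env[[km]], tag)
    }
  }
  env
}

kmer_candidates <- function(seq, env, k, step = 10L) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character(0))
  at <- unique(c(seq(1L, n, by = step), n))
  hits <- unlist(lapply(substring(seq, at, at + k - 1L),
                        function(km) env[[km]]))
  unique(hits)
}

# batched local alignments of reads against one reference sequence.
# tasks: data.frame(row, ref, strand); seqs: oriented read sequences indexed
# by `row` are computed here from `reads_chr`.
align_tasks <- function(tasks, reads_chr, refseqs, submat) {
  if (!nrow(tasks)) {
    return(cbind(tasks, score = numeric(0), sub_start = integer(0),
                 sub_end = integer(0), pat_start = integer(0),
                 pat_end = integer(0)))
  }
  key <- paste(tasks$ref, tasks$strand)
  res <- vector("list", length(unique(key)))
  i <- 0L
  for (kk in unique(key)) {
    sel <- which(key == kk)
    t1 <- tasks[sel, , drop = FALSE]
    sq <- reads_chr[t1$row]
    if (t1$strand[1L] == "-") sq <- revcomp(sq)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(sq),
      subject = Biostrings::DNAString(refseqs[[t1$ref[1L]]]),
      type = "local", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 2)
    i <- i + 1L
    res[[i]] <- cbind(t1, score = Biostrings::score(pa),
                      sub_start = Biostrings::start(Biostrings::subject(pa)),
                      sub_end = Biostrings::end(Biostrings::subject(pa)),
                      pat_start = Biostrings::start(Biostrings::pattern(pa)),
                      pat_end = Biostrings::end(Biostrings::pattern(pa)))
  }
  do.call(rbind, res)
}

#' Classify reads against the panel references
#'
#' Two-stage filter mirroring an alignment-based read triage: stage 1 aligns
#' each read locally against the insert-only reference and discards reads
#' whose best E-value exceeds the cutoff (adaptor/linker-only reads never
#' reach an alignment); stage 2 aligns survivors against the full amplicon
#' reference, keeps only the best-scoring matched segment (score ties between
#' amplicons broken by a seeded uniform random choice; a second compatible
#' segment on the same amplicon extends the matched interval to the spanning
#' region) and labels each read's PCR group from its mate and match strand:
#' mate 1 sense / mate 2 antisense are PCR-A, mate 1 antisense / mate 2 sense
#' are PCR-B.
#'
#' @param reads list with \code{r1}, \code{r2}.
#' @param refs a \code{clpp_panel_refs}.
#' @param evalue_cutoff stage-1/stage-2 E-value cutoff.
#' @param seed seed for tie breaking.
#' @param k k-mer length of the candidate search.
#' @return data.frame with one row per read mate: \code{id, mate, status,
#'   amplicon, strand, score, evalue, amp_start, amp_end} (0-based half-open
#'   matched interval on the amplicon), \code{read_start, read_end, mapq,
#'   group}.
#' @export
classify_reads <- function(reads, refs, evalue_cutoff = 1e-6, seed = 1L,
                           k = 15L) {
  if (!length(refs$inserts) || !length(refs$amplicons))
    stop("empty panel references", call. = FALSE)
  rd <- data.frame(
    id = c(names(reads$r1), names(reads$r2)),
    mate = rep(1:2, c(length(reads$r1), length(reads$r2))),
    seq = c(as.character(reads$r1), as.character(reads$r2)),
    stringsAsFactors = FALSE)
  n_rd <- nrow(rd)
  submat <- Biostrings::nucleotideSubstitutionMatrix(1, -2, baseOnly = FALSE)
  out <- data.frame(id = rd$id, mate = rd$mate,
                    status = rep("stage1_fail", n_rd),
                    amplicon = rep(NA_character_, n_rd),
                    strand = rep(NA_character_, n_rd),
                    score = rep(NA_real_, n_rd),
                    evalue = rep(NA_real_, n_rd),
                    amp_start = rep(NA_integer_, n_rd),
                    amp_end = rep(NA_integer_, n_rd),
                    read_start = rep(NA_integer_, n_rd),
                    read_end = rep(NA_integer_, n_rd),
                    mapq = rep(NA_integer_, n_rd),
                    group = rep("unassigned", n_rd),
                    stringsAsFactors = FALSE)
  if (n_rd == 0L) return(out)

  candidate_tasks <- function(rows, env) {
    cand <- lapply(rows, function(i) kmer_candidates(rd$seq[i], env, k))
    nc <- lengths(cand)
    flat <- unlist(cand, use.names = FALSE)
    if (!length(flat)) return(NULL)
    parts <- strsplit(flat, "\t", fixed = TRUE)
    data.frame(row = rep(rows, nc),
               ref = vapply(parts, `[[`, "", 1L),
               strand = vapply(parts, `[[`, "", 2L),
               stringsAsFactors = FALSE)
  }

  # stage 1: insert-only reference
  ins_idx <- kmer_index(refs$inserts, k)
  n_ins <- sum(nchar(refs$inserts))
  tasks1 <- candidate_tasks(seq_len(n_rd), ins_idx)
  pass1 <- logical(n_rd)
  if (!is.null(tasks1) && nrow(tasks1)) {
    al1 <- align_tasks(tasks1, rd$seq, refs$inserts, submat)
    best1 <- tapply(al1$score, al1$row, max)
    ev1 <- evalue_from_score(as.numeric(best1),
                             nchar(rd$seq[as.integer(names(best1))]), n_ins)
    pass1[as.integer(names(best1))] <- ev1 <= evalue_cutoff
  }

  # stage 2: full amplicon reference
  amp_idx <- kmer_index(refs$amplicons, k)
  n_amp <- sum(nchar(refs$amplicons))
  tasks2 <- candidate_tasks(which(pass1), amp_idx)
  out$status[pass1] <- "stage2_fail"
  if (is.null(tasks2) || !nrow(tasks2)) return(out)
  al2 <- align_tasks(tasks2, rd$seq, refs$amplicons, submat)
  rowsplit <- split(seq_len(nrow(al2)), al2$row)
  v <- list(status = out$status, amplicon = out$amplicon,
            strand = out$strand, score = out$score, evalue = out$evalue,
            amp_start = out$amp_start, amp_end = out$amp_end,
            read_start = out$read_start, read_end = out$read_end,
            mapq = out$mapq, group = out$group)
  rlen_all <- nchar(rd$seq)
  with_seed(seed, {
    for (sel_rows in rowsplit) {
      hits <- al2[sel_rows, , drop = FALSE]
      i <- hits$row[1L]
      rlen <- rlen_all[i]
      ev <- evalue_from_score(hits$score, rlen, n_amp)
      keep <- ev <= evalue_cutoff
      if (!any(keep)) next
      hits <- hits[keep, , drop = FALSE]
      topsel <- which(hits$score == max(hits$score))
      unique_best <- length(unique(hits$ref[topsel])) == 1L
      w <- topsel[sample.int(length(topsel), 1L)]
      sub_start <- hits$sub_start[w]; sub_end <- hits$sub_end[w]
      pat_start <- hits$pat_start[w]; pat_end <- hits$pat_end[w]
      # a second compatible matched segment on the same amplicon extends the
      # kept interval to the spanning region
      tail_len <- max(pat_start - 1L, rlen - pat_end)
      if (tail_len >= 35L) {
        tail_seq <- if (pat_start - 1L >= rlen - pat_end)
          substr(rd$seq[i], 1L, pat_start - 1L) else
            substr(rd$seq[i], pat_end + 1L, rlen)
        t2 <- data.frame(row = 1L, ref = hits$ref[w], strand = hits$strand[w],
                         stringsAsFactors = FALSE)
        a2 <- align_tasks(t2, tail_seq, refs$amplicons, submat)
        if (evalue_from_score(a2$score, nchar(tail_seq), n_amp) <=
            evalue_cutoff) {
          sub_start <- min(sub_start, a2$sub_start)
          sub_end <- max(sub_end, a2$sub_end)
        }
      }
      sense <- hits$strand[w] == "+"
      v$status[i] <- "assigned"
      v$amplicon[i] <- hits$ref[w]
      v$strand[i] <- hits$strand[w]
      v$score[i] <- hits$score[w]
      v$evalue[i] <- evalue_from_score(hits$score[w], rlen, n_amp)
      v$amp_start[i] <- sub_start - 1L
      v$amp_end[i] <- sub_end
      v$read_start[i] <- pat_start
      v$read_end[i] <- pat_end
      v$mapq[i] <- if (unique_best) 60L else 0L
      v$group[i] <- if ((rd$mate[i] == 1L) == sense) "A" else "B"
    }
  })
  for (nm in names(v)) out[[nm]] <- v[[nm]]
  out
}

#' Split classified reads into PCR-A and PCR-B read pairs
#'
#' Pairs whose mates agree (same amplicon, same group) are routed to their
#' group's files. A read whose mate was discarded is retained as a singleton:
#' the mate slot carries the first three nucleotides of the original mate as
#' a placeholder. Mates assigned to different amplicons are both demoted to
#' singletons in their own groups.
#'
#' @param assignments data.frame from \code{\link{classify_reads}}.
#' @param reads the list (\code{r1}, \code{r2}) the assignments were made
#'   from.
#' @return list with \code{A} and \code{B} (each \code{r1}, \code{r2}
#'   \code{QualityScaledDNAStringSet}) and \code{stats}.
#' @export
split_groups <- function(assignments, reads) {
  ids <- names(reads$r1)
  s1 <- as.character(reads$r1); q1 <- as.character(Biostrings::quality(reads$r1))
  s2 <- as.character(reads$r2); q2 <- as.character(Biostrings::quality(reads$r2))
  m1 <- assignments$mate == 1L
  a1 <- assignments[m1, , drop = FALSE][match(ids, assignments$id[m1]), ]
  a2 <- assignments[!m1, , drop = FALSE][match(ids, assignments$id[!m1]), ]
  ok1 <- !is.na(a1$status) & a1$status == "assigned"
  ok2 <- !is.na(a2$status) & a2$status == "assigned"
  concordant <- ok1 & ok2 & a1$amplicon == a2$amplicon & a1$group == a2$group
  cross <- ok1 & ok2 & !concordant
  single1 <- (ok1 & !ok2) | cross   # read 1 kept, mate 2 placeholder
  single2 <- (ok2 & !ok1) | cross   # read 2 kept, mate 1 placeholder
  # emit in input order: concordant pairs carry both full mates; singletons
  # keep the first three bases of the discarded mate as a placeholder
  emit <- function(sel, grp, ph) {
    i <- which(sel & grp)
    list(id = ids[i],
         s1 = if (ph == "r1") substr(s1[i], 1L, 3L) else s1[i],
         q1 = if (ph == "r1") substr(q1[i], 1L, 3L) else q1[i],
         s2 = if (ph == "r2") substr(s2[i], 1L, 3L) else s2[i],
         q2 = if (ph == "r2") substr(q2[i], 1L, 3L) else q2[i],
         ord = i)
  }
  build <- function(g) {
    parts <- list(emit(concordant, !is.na(a1$group) & a1$group == g, "none"),
                  emit(single1, !is.na(a1$group) & a1$group == g, "r2"),
                  emit(single2, !is.na(a2$group) & a2$group == g, "r1"))
    fld <- function(f) unlist(lapply(parts, `[[`, f), use.names = FALSE)
    ord <- order(fld("ord"))
    mk <- function(sq, ql, nm) {
      x <- Biostrings::DNAStringSet(sq); names(x) <- nm
      Biostrings::QualityScaledDNAStringSet(x, Biostrings::PhredQuality(ql))
    }
    nm <- fld("id")[ord]
    list(r1 = mk(fld("s1")[ord], fld("q1")[ord], nm),
         r2 = mk(fld("s2")[ord], fld("q2")[ord], nm))
  }
  list(A = build("A"), B = build("B"),
       stats = list(pairs = sum(concordant),
                    singletons = sum(single1) + sum(single2),
                    cross_amplicon = sum(cross),
                    dropped = sum(!ok1 & !ok2)))
}

# insert columns (0-based) of each amplicon lying in a tiling overlap with a
# neighbouring amplicon on the same contig
tiled_overlap_columns <- function(refs) {
  tg <- refs$targets
  out <- setNames(vector("list", nrow(tg)), tg$name)
  if (nrow(tg) < 2L) return(out)
  for (i in seq_len(nrow(tg))) for (j in seq_len(nrow(tg))) {
    if (i == j || tg$contig[i] != tg$contig[j]) next
    lo <- max(tg$start[i], tg$start[j]); hi <- min(tg$end[i], tg$end[j])
    if (lo < hi)
      out[[tg$name[i]]] <- union(out[[tg$name[i]]],
                                 seq.int(lo, hi - 1L) - tg$start[i])
  }
  out
}

#' Amplicon-anchored coverage and pileup
#'
#' Re-aligns each assigned read to its amplicon and accumulates, over insert
#' coordinates: per-base depth and allele counts (bases below
#' \code{baseq_min} are masked from depth but do not remove the read from the
#' amplicon count), simple indel events, and the per-amplicon read count A --
#' the number of reads with mapping score at least \code{mapq_min} whose
#' matched-interval midpoint lies within the amplicon insert. For tiled
#' amplicons the tiling overlap columns are excluded from both depth and
#' counting.
#'
#' @param assignments data.frame from \code{\link{classify_reads}}.
#' @param reads the read list the assignments were made from.
#' @param refs a \code{clpp_panel_refs}.
#' @param mapq_min minimum mapping score.
#' @param baseq_min minimum base quality.
#' @return object of class \code{clpp_coverage}: per-amplicon \code{depth}
#'   vectors (NA at excluded columns), \code{alleles} count matrices,
#'   \code{indels} table, \code{counts} (\code{amplicon, group, count}) and
#'   \code{excluded} columns.
#' @export
compute_coverage <- function(assignments, reads, refs, mapq_min = 30L,
                             baseq_min = 20L) {
  ids <- names(refs$amplicons)
  unknown <- setdiff(na.omit(assignments$amplicon), ids)
  if (length(unknown))
    stop("unknown amplicon id: ", unknown[1L], call. = FALSE)
  ins_len <- setNames(nchar(refs$inserts), names(refs$inserts))
  off <- refs$insert_offset
  excl <- tiled_overlap_columns(refs)
  depth <- lapply(ids, function(a) {
    d <- numeric(ins_len[[a]]); d[excl[[a]] + 1L] <- NA; d
  })
  alleles <- lapply(ids, function(a)
    matrix(0L, 4L, ins_len[[a]], dimnames = list(c("A", "C", "G", "T"), NULL)))
  names(depth) <- names(alleles) <- ids
  indel_rows <- list()
  counts <- expand.grid(amplicon = ids, group = c("A", "B"),
                        stringsAsFactors = FALSE)
  counts$count <- 0L
  sel <- which(assignments$status == "assigned" &
                 assignments$mapq >= mapq_min)
  if (!length(sel)) {
    return(structure(list(depth = depth, alleles = alleles,
                          indels = data.frame(), counts = counts,
                          excluded = excl, mapq_min = mapq_min,
                          baseq_min = baseq_min, refs_meta = refs$meta),
                     class = "clpp_coverage"))
  }
  asel <- assignments[sel, , drop = FALSE]
  s1 <- as.character(reads$r1); names(s1) <- names(reads$r1)
  q1 <- as.character(Biostrings::quality(reads$r1)); names(q1) <- names(reads$r1)
  s2 <- as.character(reads$r2); names(s2) <- names(reads$r2)
  q2 <- as.character(Biostrings::quality(reads$r2)); names(q2) <- names(reads$r2)
  rseq <- ifelse(asel$mate == 1L, s1[asel$id], s2[asel$id])
  rqual <- ifelse(asel$mate == 1L, q1[asel$id], q2[asel$id])
  neg <- asel$strand == "-"
  rseq[neg] <- revcomp(rseq[neg])
  rqual[neg] <- vapply(strsplit(rqual[neg], "", fixed = TRUE),
                       function(x) paste(rev(x), collapse = ""), "")
  submat <- Biostrings::nucleotideSubstitutionMatrix(1, -2, baseOnly = FALSE)
  key <- asel$amplicon
  for (a in unique(key)) {
    rows <- which(key == a)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(rseq[rows]),
      subject = Biostrings::DNAString(refs$amplicons[[a]]),
      type = "local", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 2)
    ap <- as.character(Biostrings::pattern(pa))
    as_ <- as.character(Biostrings::subject(pa))
    sstart <- Biostrings::start(Biostrings::subject(pa))
    pstart <- Biostrings::start(Biostrings::pattern(pa))
    o <- off[[a]]; il <- ins_len[[a]]
    ex <- excl[[a]]
    gapped <- grepl("-", ap, fixed = TRUE) | grepl("-", as_, fixed = TRUE)
    for (w in which(!gapped)) {
      # ungapped alignment: read and amplicon positions advance in lockstep
      len <- nchar(ap[w])
      qv <- utf8ToInt(rqual[rows[w]]) - 33L
      ipos <- (sstart[w] - 1L):(sstart[w] - 2L + len) - o
      rpos <- (pstart[w]):(pstart[w] - 1L + len)
      keep <- ipos >= 0L & ipos < il & !(ipos %in% ex) &
        qv[rpos] >= baseq_min
      if (!any(keep)) next
      ipk <- ipos[keep] + 1L
      depth[[a]][ipk] <- depth[[a]][ipk] + 1L
      bs <- strsplit(ap[w], "", fixed = TRUE)[[1L]][keep]
      bok <- bs %in% rownames(alleles[[a]])
      if (any(bok))
        alleles[[a]][cbind(match(bs[bok], rownames(alleles[[a]])),
                           ipk[bok])] <-
          alleles[[a]][cbind(match(bs[bok], rownames(alleles[[a]])),
                             ipk[bok])] + 1L
    }
    for (w in which(gapped)) {
      pat <- strsplit(ap[w], "", fixed = TRUE)[[1L]]
      sub <- strsplit(as_[w], "", fixed = TRUE)[[1L]]
      qv <- utf8ToInt(rqual[rows[w]]) - 33L
      ai <- sstart[w] - 1L  # 0-based amplicon pos of next subject base
      ri <- pstart[w] - 1L  # 0-based read pos of next pattern base
      j <- 1L
      while (j <= length(pat)) {
        if (sub[j] != "-" && pat[j] != "-") {
          ip <- ai - o
          if (ip >= 0L && ip < il && !(ip %in% ex) &&
              qv[ri + 1L] >= baseq_min) {
            depth[[a]][ip + 1L] <- depth[[a]][ip + 1L] + 1L
            b <- pat[j]
            if (b %in% rownames(alleles[[a]]))
              alleles[[a]][b, ip + 1L] <- alleles[[a]][b, ip + 1L] + 1L
          }
          ai <- ai + 1L; ri <- ri + 1L; j <- j + 1L
        } else if (pat[j] == "-") {  # deletion relative to the amplicon
          d0 <- ai
          while (j <= length(pat) && pat[j] == "-") {
            ai <- ai + 1L; j <- j + 1L
          }
          ip <- d0 - o - 1L  # anchor base before the deleted run
          if (ip >= 0L && ip < il)
            indel_rows[[length(indel_rows) + 1L]] <- data.frame(
              amplicon = a, insert_pos = ip, type = "del",
              seq = substr(refs$amplicons[[a]], d0 + 1L, ai),
              stringsAsFactors = FALSE)
        } else {  # insertion relative to the amplicon
          i0 <- ri
          while (j <= length(pat) && sub[j] == "-") {
            ri <- ri + 1L; j <- j + 1L
          }
          ip <- ai - o - 1L  # anchor base before the insertion
          if (ip >= 0L && ip < il)
            indel_rows[[length(indel_rows) + 1L]] <- data.frame(
              amplicon = a, insert_pos = ip, type = "ins",
              seq = substr(rseq[rows[w]], i0 + 1L, ri),
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  mid <- (asel$amp_start + asel$amp_end) %/% 2L
  ip_mid <- mid - off[asel$amplicon]
  in_insert <- ip_mid >= 0L & ip_mid < ins_len[asel$amplicon] &
    !mapply(function(a, p) p %in% excl[[a]], asel$amplicon, ip_mid)
  cnt <- table(amplicon = asel$amplicon[in_insert],
               group = asel$group[in_insert])
  for (r in seq_len(nrow(counts))) {
    a <- counts$amplicon[r]; g <- counts$group[r]
    if (a %in% rownames(cnt) && g %in% colnames(cnt))
      counts$count[r] <- as.integer(cnt[a, g])
  }
  indels <- if (length(indel_rows)) do.call(rbind, indel_rows) else
    data.frame(amplicon = character(0), insert_pos = integer(0),
               type = character(0), seq = character(0),
               stringsAsFactors = FALSE)
  structure(list(depth = depth, alleles = alleles, indels = indels,
                 counts = counts, excluded = excl, mapq_min = mapq_min,
                 baseq_min = baseq_min, refs_meta = refs$meta),
            class = "clpp_coverage")
}

#' Call variants from the amplicon pileup
#'
#' Frequency-threshold genotyper: sites with depth at least \code{min_depth}
#' are called homozygous when the alternate-allele fraction reaches
#' \code{hom_threshold} and heterozygous when it falls within
#' \code{het_band}; other sites yield no call. Simple indels fully contained
#' in reads are called from the indel tally with the same thresholds.
#'
#' @param coverage a \code{clpp_coverage}.
#' @param refs a \code{clpp_panel_refs}.
#' @param min_depth minimum depth for a call.
#' @param het_band alternate-fraction interval for a heterozygous call.
#' @param hom_threshold minimum alternate fraction for a homozygous call.
#' @return data.frame of calls: \code{contig, pos} (0-based genomic),
#'   \code{ref, alt, type, genotype, depth, alt_frac, amplicon}.
#' @export
call_variants <- function(coverage, refs, min_depth = 20L,
                          het_band = c(0.25, 0.75), hom_threshold = 0.85) {
  tg <- refs$targets
  calls <- list()
  for (a in names(coverage$alleles)) {
    al <- coverage$alleles[[a]]
    dp <- coverage$depth[[a]]
    ins_ref <- strsplit(refs$inserts[[a]], "", fixed = TRUE)[[1L]]
    t_start <- tg$start[tg$name == a]
    ctg <- tg$contig[tg$name == a]
    for (p in which(!is.na(dp) & dp >= min_depth)) {
      rb <- ins_ref[p]
      if (!rb %in% rownames(al)) next
      alt_counts <- al[setdiff(rownames(al), rb), p]
      ab <- names(alt_counts)[which.max(alt_counts)]
      frac <- alt_counts[[ab]] / dp[p]
      gt <- if (frac >= hom_threshold) "hom" else
        if (frac >= het_band[1L] && frac <= het_band[2L]) "het" else NA
      if (is.na(gt)) next
      calls[[length(calls) + 1L]] <- data.frame(
        contig = ctg, pos = t_start + p - 1L, ref = rb, alt = ab,
        type = "snv", genotype = gt, depth = dp[p], alt_frac = frac,
        amplicon = a, stringsAsFactors = FALSE)
    }
    idl <- coverage$indels[coverage$indels$amplicon == a, , drop = FALSE]
    if (nrow(idl)) {
      keytab <- table(paste(idl$insert_pos, idl$type, idl$seq, sep = "\r"))
      for (kk in names(keytab)) {
        parts <- strsplit(kk, "\r", fixed = TRUE)[[1L]]
        p <- as.integer(parts[1L]) + 1L
        if (p < 1L || p > length(dp) || is.na(dp[p]) || dp[p] < min_depth)
          next
        frac <- as.integer(keytab[[kk]]) / dp[p]
        gt <- if (frac >= hom_threshold) "hom" else
          if (frac >= het_band[1L] && frac <= het_band[2L]) "het" else NA
        if (is.na(gt)) next
        anchor <- ins_ref[p]
        if (parts[2L] == "ins") {
          refa <- anchor; alta <- paste0(anchor, parts[3L])
        } else {
          refa <- paste0(anchor, parts[3L]); alta <- anchor
        }
        calls[[length(calls) + 1L]] <- data.frame(
          contig = ctg, pos = t_start + p - 1L, ref = refa, alt = alta,
          type = parts[2L], genotype = gt, depth = dp[p],
          alt_frac = frac, amplicon = a, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(calls)) {
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      type = character(0), genotype = character(0),
                      depth = numeric(0), alt_frac = numeric(0),
                      amplicon = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write variant calls as VCF 4.2
#' @param calls data.frame from \code{\link{call_variants}}.
#' @param path output file.
#' @param contig_lengths optional named vector for contig header lines.
#' @export
write_vcf <- function(calls, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=clppkit",
           if (!is.null(contig_lengths))
             sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                     contig_lengths),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt fraction\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample")
  body <- if (nrow(calls)) {
    gt <- ifelse(calls$genotype == "hom", "1/1", "0/1")
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.4f\tGT\t%s",
            calls$contig, calls$pos + 1L, calls$ref, calls$alt,
            as.integer(calls$depth), calls$alt_frac, gt)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Fraction of amplicons within a multiplicative coverage window
#'
#' Largest fraction of amplicon counts that fit inside a window
#' \code{[c, c * width]}, over all window placements.
#'
#' @param counts per-amplicon counts.
#' @param width multiplicative window width (> 1).
#' @return fraction in \[0, 1\].
#' @export
uniformity_fraction <- function(counts, width) {
  if (width <= 1) stop("window width must exceed 1", call. = FALSE)
  counts <- counts[!is.na(counts)]
  if (!length(counts)) return(NA_real_)
  max(vapply(counts, function(c0) mean(counts >= c0 & counts <= c0 * width),
             numeric(1L)))
}

#' Ground-truth template of each read, parsed from simulator read names
#' @param ids read names from the simulator (non-blind).
#' @param captures capture table from \code{\link{simulate_capture}}.
#' @return data.frame \code{id, capture_id, pcr, amplicon_true}.
#' @export
truth_from_read_ids <- function(ids, captures) {
  parts <- strsplit(ids, ":", fixed = TRUE)
  cap <- vapply(parts, function(p) if (length(p) >= 3L) p[2L] else NA, "")
  pcr <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else NA, "")
  data.frame(id = ids, capture_id = cap, pcr = pcr,
             amplicon_true = captures$probe_id[match(cap,
                                                     captures$capture_id)],
             stringsAsFactors = FALSE)
}

#' Capture performance metrics
#'
#' Computes the panel's standard performance report: sensitivity (percent of
#' target bases at or above the depth threshold, with the threshold also
#' expressed relative to mean coverage), specificity (percent of
#' filter-passed reads assigned to their intended targets when read truth is
#' available, otherwise percent assigned at all), uniformity (largest
#' fraction of amplicons within a 50- and 100-fold multiplicative coverage
#' window), genotype concordance against truth variants, and the rank-order
#' (Spearman) correlation against a second sample's amplicon counts.
#'
#' @param coverage a \code{clpp_coverage}.
#' @param assignments data.frame from \code{\link{classify_reads}}.
#' @param refs a \code{clpp_panel_refs}.
#' @param calls optional calls from \code{\link{call_variants}}.
#' @param truth_variants optional truth table from the genome simulator.
#' @param truth_reads optional data.frame from
#'   \code{\link{truth_from_read_ids}}.
#' @param other_counts optional second sample's per-amplicon counts for the
#'   reproducibility correlation.
#' @param depth_threshold sensitivity depth threshold.
#' @param fold_windows uniformity window widths.
#' @return named list of metrics (percentages on a 0--100 scale).
#' @export
capture_metrics <- function(coverage, assignments, refs, calls = NULL,
                            truth_variants = NULL, truth_reads = NULL,
                            other_counts = NULL, depth_threshold = 20L,
                            fold_windows = c(50, 100)) {
  dp <- unlist(coverage$depth)
  dp <- dp[!is.na(dp)]
  mean_cov <- mean(dp)
  sens <- 100 * mean(dp >= depth_threshold)
  passed <- assignments$status %in% c("assigned", "stage2_fail")
  assigned <- assignments$status == "assigned"
  if (!is.null(truth_reads)) {
    tr <- truth_reads$amplicon_true[match(assignments$id, truth_reads$id)]
    spec <- 100 * sum(assigned & !is.na(tr) & assignments$amplicon == tr) /
      max(1L, sum(passed))
  } else {
    spec <- 100 * sum(assigned) / max(1L, sum(passed))
  }
  amp_counts <- tapply(coverage$counts$count, coverage$counts$amplicon, sum)
  unif <- vapply(fold_windows, function(f)
    100 * uniformity_fraction(as.numeric(amp_counts), f), numeric(1L))
  names(unif) <- paste0("uniformity_", fold_windows, "fold")
  conc <- NA_real_; n_eval <- NA_integer_
  if (!is.null(truth_variants) && !is.null(calls)) {
    cc <- genotype_concordance(calls, truth_variants, coverage, refs,
                               min_depth = depth_threshold)
    conc <- cc$concordance; n_eval <- cc$n_eval
  }
  repro <- if (!is.null(other_counts)) {
    cor(as.numeric(amp_counts[names(other_counts)]),
        as.numeric(other_counts), method = "spearman")
  } else NA_real_
  c(list(sensitivity = sens,
         depth_threshold = depth_threshold,
         depth_threshold_rel_mean = depth_threshold / mean_cov,
         mean_coverage = mean_cov,
         specificity = spec),
    as.list(unif),
    list(concordance = conc, concordance_sites = n_eval,
         reproducibility_spearman = repro))
}

#' Genotype concordance of calls against planted truth
#'
#' Evaluates truth variants lying inside panel inserts whose pileup depth
#' reaches \code{min_depth}; a site is concordant when a call exists at its
#' position with the planted alternate allele and genotype.
#'
#' @param calls data.frame from \code{\link{call_variants}}.
#' @param truth_variants truth table from the genome simulator.
#' @param coverage a \code{clpp_coverage}.
#' @param refs a \code{clpp_panel_refs}.
#' @param min_depth evaluation depth threshold.
#' @return list with \code{n_eval} and \code{concordance} (percent).
#' @export
genotype_concordance <- function(calls, truth_variants, coverage, refs,
                                 min_depth = 20L) {
  tg <- refs$targets
  n_eval <- 0L; n_conc <- 0L
  for (i in seq_len(nrow(truth_variants))) {
    tv <- truth_variants[i, ]
    hit <- tg[tg$contig == tv$contig & tg$start <= tv$pos &
                tg$end > tv$pos, , drop = FALSE]
    if (!nrow(hit)) next
    a <- hit$name[1L]
    ip <- tv$pos - hit$start[1L]
    dpv <- coverage$depth[[a]]
    if (ip + 1L > length(dpv) || is.na(dpv[ip + 1L]) ||
        dpv[ip + 1L] < min_depth) next
    n_eval <- n_eval + 1L
    cl <- calls[calls$contig == tv$contig & calls$pos == tv$pos, ,
                drop = FALSE]
    if (!nrow(cl)) next
    alt_match <- if (tv$type == "snv") any(cl$alt == tv$alt & cl$type == "snv")
      else any(cl$type == tv$type)
    if (alt_match && any(cl$genotype == tv$genotype)) n_conc <- n_conc + 1L
  }
  list(n_eval = n_eval,
       concordance = if (n_eval) 100 * n_conc / n_eval else NA_real_)
}
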