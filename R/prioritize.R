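# combine LD expansion with epigenomic and 3D-interaction evidence into the
# ranked candidate-functional-SNP table.

#' Does a SNP fall inside any interval?
#'
#' Point-in-interval test on the same chromosome.  In BED (0-based half-open)
#' terms a SNP at 0-based position p overlaps an interval iff
#' `start <= p < end`; the GRanges representation used here preserves exactly
#' that semantics.
#'
#' @param snp a [variantRecord()].
#' @param intervals a `GRanges` (e.g. from [readIntervals()]).
#' @return list(hit = logical, matches = indices of overlapping intervals).
#' @export
snpInIntervals <- function(snp, intervals) {
  if (length(intervals) == 0) return(list(hit = FALSE, matches = integer()))
  # cross-chromosome queries are routine; silence the combined-seqlevels note
  ov <- suppressWarnings(GenomicRanges::findOverlaps(.snp_granges(snp),
                                                     intervals))
  idx <- S4Vectors::subjectHits(ov)
  list(hit = length(idx) > 0, matches = idx)
}

#' Does a SNP-containing anchor loop to a target region?
#'
#' TRUE iff some interaction has one anchor containing the SNP and the other
#' anchor overlapping the target interval; the anchor pair is unordered.
#'
#' @param snp a [variantRecord()].
#' @param interactions an [InteractionPairs-class].
#' @param target a length-1 `GRanges` (e.g. a gene 3' end window).
#' @return list(hit = logical, support = indices of supporting interactions).
#' @export
snpInteractsRegion <- function(snp, interactions, target) {
  if (length(interactions) == 0) return(list(hit = FALSE, support = integer()))
  sg <- .snp_granges(snp)
  a1 <- anchorOne(interactions); a2 <- anchorTwo(interactions)
  in1 <- suppressWarnings(IRanges::overlapsAny(a1, sg))
  in2 <- suppressWarnings(IRanges::overlapsAny(a2, sg))
  t1 <- suppressWarnings(IRanges::overlapsAny(a1, target))
  t2 <- suppressWarnings(IRanges::overlapsAny(a2, target))
  support <- which((in1 & t2) | (in2 & t1))
  list(hit = length(support) > 0, support = support)
}

#' Build the candidate-functional-SNP evidence table
#'
#' Expands the tag SNP to its high-LD proxies ([ldExpand()]), then annotates
#' each candidate with: per-peak-set open-chromatin flags (union flag
#' `in_dhs`), an enhancer-mark flag (`in_h3k4me1`), whether a SNP-containing
#' interaction anchor loops to the target region (`interacts_target`), and —
#' for candidates passing the open-chromatin gate — allele-specific motif
#' disruption results for each PWM.  Rows are sorted by
#' (interacts_target, number of true evidence flags, r2), all descending.
#'
#' @param panel a [HaplotypePanel-class] containing the tag and candidates.
#' @param tag tag SNP id.
#' @param peak_sets named list of `GRanges` open-chromatin peak sets.
#' @param h3k4me1 optional `GRanges` of enhancer-mark peaks.
#' @param interactions optional [InteractionPairs-class].
#' @param target optional length-1 `GRanges` target region (e.g. the 3'-most
#'   5 kb of the candidate gene).
#' @param pwms optional list of [PWMotif-class] for motif scanning.
#' @param sequences named list, per candidate id, of
#'   `list(seq_ref, seq_alt)` 51-mers centered on the SNP; candidates passing
#'   the gate but lacking sequences are warned about and left unscanned.
#' @param r2_min,maf_min,window LD-expansion gates (defaults 0.8 / 0.05 / 1e6).
#' @param motif_gate only scan motifs for candidates inside open chromatin
#'   (default TRUE, mirroring staged prioritization); set FALSE to scan all.
#' @param fimo_threshold,n_sim,seed motif-scan parameters.
#' @return data.frame, one row per candidate: variant, pos, r2_to_tag,
#'   dprime_to_tag, maf, one `in_<set>` column per peak set, in_dhs,
#'   in_h3k4me1, interacts_target, n_evidence, motif_best_pwm, motif_delta,
#'   motif_p.  Full per-PWM disruption results are in
#'   `attr(x, "motif_results")`.
#' @export
buildEvidenceTable <- function(panel, tag, peak_sets = list(),
                               h3k4me1 = NULL, interactions = NULL,
                               target = NULL, pwms = list(),
                               sequences = list(), r2_min = 0.8,
                               maf_min = 0.05, window = 1e6,
                               motif_gate = TRUE, fimo_threshold = 1e-3,
                               n_sim = 1000, seed = 1) {
  ld <- ldExpand(panel, tag, r2_min = r2_min, maf_min = maf_min,
                 window = window)
  v <- variantInfo(panel)
  motif_results <- list()
  rows <- lapply(seq_len(nrow(ld)), function(i) {
    id <- ld$variant[i]
    k <- match(id, v$id)
    snp <- variantRecord(id, v$chrom[k], v$pos[k], v$ref[k], v$alt[k])
    peak_flags <- vapply(peak_sets, function(gr) snpInIntervals(snp, gr)$hit,
                         FALSE)
    in_dhs <- length(peak_flags) > 0 && any(peak_flags)
    in_h3k4me1 <- !is.null(h3k4me1) && snpInIntervals(snp, h3k4me1)$hit
    interacts <- !is.null(interactions) && !is.null(target) &&
      snpInteractsRegion(snp, interactions, target)$hit
    maf <- min(ld$pB[i], 1 - ld$pB[i])

    motif_best <- data.frame(motif_best_pwm = NA_character_,
                             motif_delta = NA_real_, motif_p = NA_real_)
    if (length(pwms) && (in_dhs || !motif_gate)) {
      sq <- sequences[[id]]
      if (is.null(sq)) {
        warning("no sequence window for gated candidate '", id,
                "': motif fields left empty", call. = FALSE)
      } else {
        res <- lapply(pwms, function(p) tryCatch(
          disruptionSignificance(p, sq$seq_ref, sq$seq_alt, n_sim = n_sim,
                                 seed = seed, threshold = fimo_threshold),
          error = function(e) NULL))
        res <- Filter(Negate(is.null), res)
        motif_results[[id]] <<- res
        if (length(res)) {
          best <- res[[which.min(vapply(res, `[[`, 0, "p_empirical"))]]
          motif_best <- data.frame(motif_best_pwm = best$pwm,
                                   motif_delta = best$delta,
                                   motif_p = best$p_empirical)
        }
      }
    }
    flags <- data.frame(t(peak_flags))  # 1 row, 0 columns when no peak sets
    if (length(peak_flags)) names(flags) <- paste0("in_", names(peak_sets))
    cbind(data.frame(variant = id, chrom = snp$chrom, pos = snp$pos,
                     r2_to_tag = ld$r2[i], dprime_to_tag = ld$Dprime[i],
                     maf = maf),
          flags,
          data.frame(in_dhs = in_dhs, in_h3k4me1 = in_h3k4me1,
                     interacts_target = interacts),
          motif_best)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$n_evidence <- out$in_dhs + out$in_h3k4me1 + out$interacts_target
  out <- out[order(-out$interacts_target, -out$n_evidence, -out$r2_to_tag,
                   out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "motif_results") <- motif_results
  out
}
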