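# PWM log-odds scanning with exact score p-values, and the empirical
# null-mutation significance test for allele-specific motif disruption.
#
# Scores are natural-log odds log(p/bg) summed over positions.  For the exact
# p-value the per-position scores are discretized to integers at bin width
# 0.001 (scores x 1000, rounded) and the null score distribution under the
# background model is built by dynamic-programming convolution.

.SCORE_BIN <- 1e-3

.seq_chars <- function(s) {
  x <- strsplit(toupper(s), "")[[1]]
  bad <- !(x %in% DNA_BASES4)
  if (any(bad)) stop("non-ACGT base '", x[which(bad)[1]], "' at position ",
                     which(bad)[1], call. = FALSE)
  x
}

# log-odds matrix (4 x L) in nats
.lo_matrix <- function(pwm) log(pwmProbs(pwm) / pwmBackground(pwm))

# reverse-complement log-odds matrix: reverse columns, complement rows
.rc_rows <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G
.rc_lo <- function(lo) lo[.rc_rows, rev(seq_len(ncol(lo))), drop = FALSE]

#' Log-odds score of a k-mer under a PWM
#'
#' Sum over positions of `log(prob(base) / background(base))`, with the
#' probabilities pseudocount-smoothed at load.
#'
#' @param pwm a [PWMotif-class].
#' @param kmer string over ACGT of exactly the motif length.
#' @return numeric score in nats.
#' @export
logoddsScore <- function(pwm, kmer) {
  x <- .seq_chars(kmer)
  .assert(length(x) == length(pwm), "kmer length ", length(x),
          " != motif length ", length(pwm))
  lo <- .lo_matrix(pwm)
  sum(lo[cbind(match(x, DNA_BASES4), seq_along(x))])
}

# exact distribution of the discretized log-odds score of a background k-mer.
# Returns list(offset = smallest integer score, mass = probability vector)
# for the given 4 x L log-odds matrix and background.
.score_dist <- function(lo, background, bin = .SCORE_BIN) {
  sint <- round(lo / bin)
  lo_min <- cumsum(apply(sint, 2, min))
  lo_max <- cumsum(apply(sint, 2, max))
  L <- ncol(sint)
  mass <- 1; off <- 0L
  for (j in seq_len(L)) {
    newoff <- lo_min[j]
    new <- numeric(lo_max[j] - lo_min[j] + 1L)
    for (b in 1:4) {
      sh <- off + sint[b, j] - newoff  # 0-based shift into `new`
      idx <- seq_along(mass) + sh
      new[idx] <- new[idx] + background[b] * mass
    }
    mass <- new; off <- as.integer(newoff)
  }
  list(offset = off, mass = mass)
}

# upper-tail probability P(score_int >= round(score / bin)) from a .score_dist
.tail_p <- function(dist, score, bin = .SCORE_BIN) {
  s <- round(score / bin)
  lo <- dist$offset; hi <- dist$offset + length(dist$mass) - 1L
  if (s <= lo) return(1)
  if (s > hi) return(min(dist$mass[dist$mass > 0]))  # beyond max: smallest mass
  p <- sum(dist$mass[(s - lo + 1L):length(dist$mass)])
  max(p, min(dist$mass[dist$mass > 0]))
}

#' Exact p-value of a log-odds score under the background model
#'
#' `P(score(K) >= score)` for a k-mer K drawn i.i.d. from the PWM's
#' background, computed exactly by dynamic programming over the discretized
#' (bin width 0.001) per-position score distribution.  Scores beyond the
#' maximum achievable return the smallest representable positive mass, so the
#' result is always in (0, 1].
#'
#' @inheritParams logoddsScore
#' @param score finite numeric score (nats).
#' @return p-value in (0, 1]; non-increasing in `score`.
#' @export
scorePvalue <- function(pwm, score) {
  .assert(is.finite(score), "score must be finite")
  .tail_p(.score_dist(.lo_matrix(pwm), pwmBackground(pwm)), score)
}

# score every window of `x` (character vector) against log-odds matrix `lo`
.window_scores <- function(x, lo) {
  L <- ncol(lo)
  n <- length(x) - L + 1L
  idx <- match(x, DNA_BASES4)
  vapply(seq_len(n), function(o)
    sum(lo[cbind(idx[o:(o + L - 1L)], seq_len(L))]), 0)
}

# scan one sequence on both strands; returns all windows (unthresholded)
.scan_seq <- function(pwm, x, dists) {
  lo_f <- .lo_matrix(pwm); lo_r <- .rc_lo(lo_f)
  L <- ncol(lo_f)
  center <- 25L  # 0-based central position of the 51-mer
  offs <- 0:(length(x) - L)
  sf <- .window_scores(x, lo_f)
  sr <- .window_scores(x, lo_r)
  data.frame(
    pwm = pwmName(pwm),
    offset = rep(offs, 2L),
    strand = rep(c("+", "-"), each = length(offs)),
    score = c(sf, sr),
    p = c(vapply(sf, .tail_p, 0, dist = dists$fwd),
          vapply(sr, .tail_p, 0, dist = dists$rev)),
    covers_center = rep(offs <= center & center <= offs + L - 1L, 2L))
}

# memoized per-PWM forward/reverse score distributions (the DP is the
# dominant cost of a scan; repeated calls on the same matrix are common)
.dist_cache <- new.env(parent = emptyenv())

.allele_dists <- function(pwm) {
  key <- paste(c(pwm@name, dim(pwm@probs), signif(pwm@probs, 12),
                 signif(pwm@background, 12)), collapse = ",")
  hit <- .dist_cache[[key]]
  if (!is.null(hit)) return(hit)
  lo <- .lo_matrix(pwm)
  bg <- pwmBackground(pwm)
  val <- list(fwd = .score_dist(lo, bg),
              rev = .score_dist(.rc_lo(lo), bg[.rc_rows]))
  if (length(ls(.dist_cache)) > 64) rm(list = ls(.dist_cache),
                                       envir = .dist_cache)
  .dist_cache[[key]] <- val
  val
}

#' Scan both alleles of a SNP-centered 51-mer for motif hits
#'
#' FIMO-style scan: every offset on both strands is scored; windows whose
#' exact score p-value is `<= threshold` are reported as hits, annotated with
#' whether they cover the central (SNP) base.  Minus-strand hits score the
#' reverse-complemented motif against the forward sequence; offsets always
#' refer to the forward sequence, 0-based.
#'
#' @inheritParams logoddsScore
#' @param seq_ref,seq_alt length-51 sequences differing only at the central
#'   position (0-based offset 25); they may also be identical.
#' @param threshold score p-value cutoff (default 1e-3).
#' @return list(hits_ref, hits_alt): data.frames with columns pwm, offset,
#'   strand, score, p, covers_center.
#' @export
scanAlleles <- function(pwm, seq_ref, seq_alt, threshold = 1e-3) {
  xr <- .seq_chars(seq_ref); xa <- .seq_chars(seq_alt)
  .assert(length(xr) == 51 && length(xa) == 51, "sequences must be 51 bp")
  diffs <- which(xr != xa)
  .assert(length(diffs) == 0 || identical(diffs, 26L),
          "alleles must differ only at the central base (position 26)")
  dists <- .allele_dists(pwm)
  hr <- .scan_seq(pwm, xr, dists)
  ha <- .scan_seq(pwm, xa, dists)
  list(hits_ref = hr[hr$p <= threshold, , drop = FALSE],
       hits_alt = ha[ha$p <= threshold, , drop = FALSE])
}

# best center-covering window (unthresholded); ties -> smaller offset, then +
.best_center <- function(pwm, x, dists) {
  all_w <- .scan_seq(pwm, x, dists)
  cc <- all_w[all_w$covers_center, , drop = FALSE]
  cc <- cc[order(-cc$score, cc$offset, cc$strand), , drop = FALSE]
  cc[1, , drop = FALSE]
}

#' Empirical significance of allele-specific motif disruption
#'
#' The observed statistic is `|delta|`, the difference between the best
#' center-covering window scores of the alternate and reference alleles (best
#' taken over all offsets covering the SNP and both strands, without the hit
#' threshold — the threshold only decides whether a motif is present at all).
#' The null ensemble simulates null mutations in motif sequences: a
#' motif-length sequence is drawn from the PWM, one uniformly chosen position
#' is mutated to a uniformly chosen different base, and the score change is
#' recorded; `n_sim` draws give
#' `p = (1 + #(|delta_null| >= |delta_obs|)) / (1 + n_sim)`.
#' Disruption vs creation is the sign of `delta`; significance is two-sided.
#'
#' @inheritParams scanAlleles
#' @param n_sim number of null draws (default 10000).
#' @param seed integer RNG seed (mandatory; results are reproducible).
#' @return list(pwm, best_hit_ref, best_hit_alt, delta, p_empirical, n_sim,
#'   seed); `best_hit_ref`/`best_hit_alt` are one-row data.frames (NULL when
#'   that allele has no center-covering hit at the threshold).
#' @export
disruptionSignificance <- function(pwm, seq_ref, seq_alt, n_sim = 10000,
                                   seed, threshold = 1e-3) {
  .assert(!missing(seed), "seed is mandatory")
  hits <- scanAlleles(pwm, seq_ref, seq_alt, threshold = threshold)
  ref_cc <- hits$hits_ref[hits$hits_ref$covers_center, , drop = FALSE]
  alt_cc <- hits$hits_alt[hits$hits_alt$covers_center, , drop = FALSE]
  if (nrow(ref_cc) == 0 && nrow(alt_cc) == 0)
    stop("no motif to disrupt: neither allele has a center-covering hit at ",
         "threshold ", threshold, call. = FALSE)
  dists <- .allele_dists(pwm)
  best_ref <- .best_center(pwm, .seq_chars(seq_ref), dists)
  best_alt <- .best_center(pwm, .seq_chars(seq_alt), dists)
  delta <- best_alt$score - best_ref$score

  lo <- .lo_matrix(pwm)
  probs <- pwmProbs(pwm)
  L <- ncol(lo)
  delta_null <- local_seed(seed, {
    u <- sample.int(L, n_sim, replace = TRUE)
    r <- runif(n_sim)
    cum <- apply(probs, 2, cumsum)          # 4 x L
    old <- 1L + rowSums(t(cum[, u, drop = FALSE]) < r)
    j <- sample.int(3L, n_sim, replace = TRUE)
    newb <- ifelse(j >= old, j + 1L, j)     # uniform over the 3 other bases
    lo[cbind(newb, u)] - lo[cbind(old, u)]
  })
  p_emp <- (1 + sum(abs(delta_null) >= abs(delta))) / (1 + n_sim)
  pick <- function(h) if (nrow(h)) {
    h <- h[order(-h$score, h$offset, h$strand), , drop = FALSE]
    h[1, , drop = FALSE]
  } else NULL
  list(pwm = pwmName(pwm), best_hit_ref = pick(ref_cc),
       best_hit_alt = pick(alt_cc), delta = delta, p_empirical = p_emp,
       n_sim = n_sim, seed = seed)
}
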