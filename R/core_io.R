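# readers/writers for the on-disk formats the pipeline touches.
# Intervals are stored internally as GRanges (1-based closed); BED/BEDPE
# 0-based half-open coordinates are converted at this boundary only.

.is_vcf <- function(path) {
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path)) return(TRUE)
  first <- readLines(path, n = 1L)
  grepl("^##fileformat=VCF", first)
}

#' Read phased haplotypes from VCF or the haplotype TSV dialect
#'
#' VCF input must carry fully phased GT fields (`a|b`); each sample contributes
#' two haplotype rows.  Multiallelic records are rejected unless
#' `split_multiallelic = TRUE`, in which case each alternate allele becomes a
#' biallelic pseudo-variant with the id suffixed `_<k>`.  The TSV dialect is
#' the one written by [writeHaplotypes()]: `##variant=id,chrom,pos,ref,alt`
#' header lines followed by a table with columns haplotype, sample, population
#' and one 0/1 column per variant.
#'
#' @param path VCF (possibly gzipped) or haplotype TSV file.
#' @param population optional population label; keeps only haplotypes whose
#'   sample carries that label (see `populations`).
#' @param populations named character vector mapping sample id to population
#'   label, used for VCF input (the TSV dialect stores labels itself).
#' @param split_multiallelic split multiallelic VCF records instead of erroring.
#' @return A [HaplotypePanel-class].
#' @seealso [writeHaplotypes()]
#' @export
readHaplotypes <- function(path, population = NULL, populations = NULL,
                           split_multiallelic = FALSE) {
  panel <- if (.is_vcf(path)) {
    .read_haplotypes_vcf(path, populations, split_multiallelic)
  } else {
    .read_haplotypes_tsv(path)
  }
  if (!is.null(population)) {
    keep <- panel@population == population
    .assert(any(keep), "no haplotypes labeled with population '", population, "'")
    panel <- panel[keep, ]
  }
  panel
}

.read_haplotypes_vcf <- function(path, populations, split_multiallelic) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  .assert(!is.null(gt), "VCF has no GT field: ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ids <- names(rr)
  ref <- as.character(rr$REF)
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)

  bad <- which(matrix(grepl("/", gt), nrow = nrow(gt)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("unphased genotype in sample '", colnames(gt)[bad[1, 2]],
         "' at record '", ids[bad[1, 1]], "'", call. = FALSE)
  }
  .assert(!any(gt == "." | grepl("\\.", gt)),
          "missing genotypes are not supported in the phased dialect: ", path)

  if (any(n_alt > 1) && !split_multiallelic)
    stop("multiallelic record(s): ", paste(ids[n_alt > 1], collapse = ", "),
         " (set split_multiallelic = TRUE to split)", call. = FALSE)

  samples <- colnames(gt)
  # 2 haplotypes per sample, interleaved
  sp <- strsplit(as.vector(t(gt)), "|", fixed = TRUE)
  codes <- matrix(as.integer(unlist(sp)), ncol = 2, byrow = TRUE)
  # codes rows ordered (variant-major over samples); build hap x variant code matrix
  nv <- length(ids); ns <- length(samples)
  hapcode <- matrix(0L, nrow = 2 * ns, ncol = nv)
  for (h in 1:2) {
    hapcode[seq(h, 2 * ns, by = 2), ] <-
      matrix(codes[, h], nrow = ns, ncol = nv, byrow = FALSE)
  }

  out_alleles <- list(); out_var <- list()
  for (k in seq_len(nv)) {
    alts <- as.character(altl[[k]])
    if (length(alts) == 1L) {
      out_alleles[[length(out_alleles) + 1L]] <- as.integer(hapcode[, k] == 1L)
      out_var[[length(out_var) + 1L]] <-
        data.frame(id = ids[k], chrom = as.character(GenomicRanges::seqnames(rr)[k]),
                   pos = GenomicRanges::start(rr)[k], ref = ref[k], alt = alts)
    } else {
      for (a in seq_along(alts)) {
        out_alleles[[length(out_alleles) + 1L]] <- as.integer(hapcode[, k] == a)
        out_var[[length(out_var) + 1L]] <-
          data.frame(id = paste0(ids[k], "_", a),
                     chrom = as.character(GenomicRanges::seqnames(rr)[k]),
                     pos = GenomicRanges::start(rr)[k], ref = ref[k], alt = alts[a])
      }
    }
  }
  variants <- do.call(rbind, out_var)
  alleles <- do.call(cbind, out_alleles)
  colnames(alleles) <- variants$id
  hap_samples <- rep(samples, each = 2)
  pop <- if (is.null(populations)) rep("ALL", length(hap_samples))
         else unname(populations[hap_samples])
  HaplotypePanel(alleles, variants, samples = hap_samples, population = pop)
}

.read_haplotypes_tsv <- function(path) {
  lines <- readLines(path)
  vh <- grep("^##variant=", lines, value = TRUE)
  .assert(length(vh) > 0, "haplotype TSV is missing ##variant= header lines: ", path)
  vparts <- strsplit(sub("^##variant=", "", vh), ",", fixed = TRUE)
  variants <- data.frame(
    id = vapply(vparts, `[`, "", 1L), chrom = vapply(vparts, `[`, "", 2L),
    pos = as.integer(vapply(vparts, `[`, "", 3L)),
    ref = vapply(vparts, `[`, "", 4L), alt = vapply(vparts, `[`, "", 5L))
  body <- lines[!grepl("^##", lines)]
  tab <- read.table(text = body, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  .assert(all(c("haplotype", "sample", "population") %in% names(tab)),
          "haplotype TSV needs columns haplotype, sample, population")
  .assert(all(variants$id %in% names(tab)),
          "haplotype TSV body is missing declared variant columns")
  alleles <- as.matrix(tab[, variants$id, drop = FALSE])
  storage.mode(alleles) <- "integer"
  rownames(alleles) <- tab$haplotype
  HaplotypePanel(alleles, variants, samples = tab$sample,
                 population = tab$population)
}

#' Write a HaplotypePanel in the haplotype TSV dialect
#'
#' @param panel a [HaplotypePanel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeHaplotypes <- function(panel, path) {
  v <- variantInfo(panel)
  hdr <- sprintf("##variant=%s,%s,%d,%s,%s", v$id, v$chrom, v$pos, v$ref, v$alt)
  body <- data.frame(haplotype = rownames(alleleMatrix(panel)),
                     sample = sampleIds(panel),
                     population = populations(panel),
                     check.names = FALSE)
  body <- cbind(body, as.data.frame(alleleMatrix(panel), check.names = FALSE))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genomic intervals from BED3+ text
#'
#' BED coordinates (0-based half-open) are converted to the 1-based closed
#' GRanges convention.  Columns 4 and 5, when present, populate the `name` and
#' `score` metadata columns.
#'
#' @param path BED file; `track`/`browser`/`#` lines are skipped.
#' @return A `GRanges`; empty input yields an empty `GRanges`.
#' @export
readIntervals <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(GenomicRanges::GRanges(name = character(), score = numeric()))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED line ", lineno[which(nf < 3)[1]], ": fewer than 3 columns", call. = FALSE)
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop("BED line ", lineno[bad[1]], ": non-numeric coordinates", call. = FALSE)
  bad <- which(start0 >= end0)
  if (length(bad))
    stop("BED line ", lineno[bad[1]], ": start >= end (", start0[bad[1]], " >= ",
         end0[bad[1]], ")", call. = FALSE)
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[4] %||% NA_character_, ""), NA_character_)
  score <- suppressWarnings(
    as.numeric(ifelse(nf >= 5, vapply(fields, function(f) f[5] %||% NA_character_, ""), NA)))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                         name = name, score = score)
}

#' Write GRanges as BED
#'
#' @param gr a GRanges; metadata columns `name` and `score` are emitted as BED
#'   columns 4-5 when present.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeIntervals <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  mc <- GenomicRanges::mcols(gr)
  if ("name" %in% names(mc)) {
    df$name <- ifelse(is.na(mc$name), ".", as.character(mc$name))
    if ("score" %in% names(mc) && any(!is.na(mc$score)))
      df$score <- ifelse(is.na(mc$score), 0, mc$score)
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read chromatin interactions from BEDPE text
#'
#' Dialect: six 0-based half-open coordinate columns
#' (chrom1,start1,end1,chrom2,start2,end2) plus an optional seventh score
#' column.  Anchor pairs are unordered (canonically sorted on load).
#'
#' @param path BEDPE file.
#' @return An [InteractionPairs-class].
#' @export
readInteractions <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(InteractionPairs(GenomicRanges::GRanges(), GenomicRanges::GRanges(),
                            numeric()))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 6)
  if (length(bad))
    stop("BEDPE line ", lineno[bad[1]], ": expected >= 6 columns, got ",
         nf[bad[1]], call. = FALSE)
  num <- function(i) suppressWarnings(as.numeric(vapply(fields, `[`, "", i)))
  chr1 <- vapply(fields, `[`, "", 1L); chr2 <- vapply(fields, `[`, "", 4L)
  s1 <- num(2); e1 <- num(3); s2 <- num(5); e2 <- num(6)
  bad <- which(is.na(s1) | is.na(e1) | is.na(s2) | is.na(e2))
  if (length(bad))
    stop("BEDPE line ", lineno[bad[1]], ": non-numeric coordinates", call. = FALSE)
  bad <- which(s1 >= e1 | s2 >= e2)
  if (length(bad))
    stop("BEDPE line ", lineno[bad[1]], ": start >= end", call. = FALSE)
  score <- if (any(nf >= 7)) {
    suppressWarnings(as.numeric(ifelse(nf >= 7,
      vapply(fields, function(f) f[7] %||% NA_character_, ""), NA)))
  } else rep(0, length(lines))
  score[is.na(score)] <- 0
  InteractionPairs(
    GenomicRanges::GRanges(chr1, IRanges::IRanges(s1 + 1, e1)),
    GenomicRanges::GRanges(chr2, IRanges::IRanges(s2 + 1, e2)),
    score)
}

#' Write InteractionPairs as BEDPE
#'
#' @param pairs an [InteractionPairs-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeInteractions <- function(pairs, path) {
  a1 <- anchorOne(pairs); a2 <- anchorTwo(pairs)
  df <- data.frame(
    as.character(GenomicRanges::seqnames(a1)), GenomicRanges::start(a1) - 1L,
    GenomicRanges::end(a1),
    as.character(GenomicRanges::seqnames(a2)), GenomicRanges::start(a2) - 1L,
    GenomicRanges::end(a2), interactionScores(pairs))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read JASPAR-style position frequency matrices
#'
#' Multi-record files of the form `>ID name` followed by four rows labeled
#' A, C, G, T with whitespace-separated counts or probabilities, optionally
#' bracketed (`A [ 1 2 3 ]`).  Columns are pseudocount-smoothed and normalized
#' to probabilities at load (see [PWMotif()]).
#'
#' @param path PFM file.
#' @param background length-4 background frequencies (default uniform).
#' @param pseudocount smoothing constant, default 0.1.
#' @return A list of [PWMotif-class] objects, named by motif id.
#' @export
readPwm <- function(path, background = rep(0.25, 4), pseudocount = 0.1) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  .assert(length(starts) > 0, "no '>' motif headers in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (m in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[m]])
    name <- strsplit(hdr, "\\s+")[[1]][1]
    body <- lines[(starts[m] + 1L):ends[m]]
    .assert(length(body) == 4, "PWM '", name, "': expected 4 base rows")
    lab <- toupper(sub("^\\s*(\\S).*$", "\\1", body))
    if (!setequal(lab, DNA_BASES4))
      stop("PWM '", name, "': row labels must be A, C, G, T (got ",
           paste(lab, collapse = ","), ")", call. = FALSE)
    vals <- lapply(body, function(l) {
      l <- gsub("[][]", " ", l)
      v <- strsplit(trimws(l), "\\s+")[[1]][-1]
      as.numeric(v)
    })
    len <- lengths(vals)
    .assert(length(unique(len)) == 1, "PWM '", name, "': ragged rows")
    mat <- do.call(rbind, vals)
    rownames(mat) <- lab
    out[[name]] <- PWMotif(name, mat[DNA_BASES4, , drop = FALSE],
                           background = background, pseudocount = pseudocount)
  }
  out
}

#' Write PWMotif objects in the JASPAR PFM dialect
#'
#' Emits the smoothed probability matrices; reading back with
#' `pseudocount = 0` reproduces them exactly.
#'
#' @param pwms a [PWMotif-class] or list thereof.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePwm <- function(pwms, path) {
  if (is(pwms, "PWMotif")) pwms <- list(pwms)
  con <- file(path, "w"); on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", pwmName(p)), con)
    pr <- pwmProbs(p)
    for (b in DNA_BASES4)
      writeLines(paste(b, "[", paste(format(pr[b, ], digits = 17), collapse = " "), "]"),
                 con)
  }
  invisible(path)
}

#' Read/write a feature-by-sample TSV matrix
#'
#' Dialect: header row of sample ids, first column of feature ids.
#'
#' @param path TSV file.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
readTsvMatrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  m
}

#' @rdname readTsvMatrix
#' @param mat numeric matrix with rownames and colnames.
#' @param feature_col header label of the feature-id column (default "feature").
#' @export
writeTsvMatrix <- function(mat, path, feature_col = "feature") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- feature_col
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a GWAS catalog table
#'
#' TSV with header columns snp_id, chrom, pos, trait, category, p_value;
#' duplicate (snp_id, trait) rows are deduplicated on load.
#'
#' @param path TSV file.
#' @return A [GwasCatalog-class].
#' @export
readGwasCatalog <- function(path) {
  GwasCatalog(data.table::fread(path, sep = "\t", header = TRUE,
                                data.table = FALSE))
}

#' @rdname readGwasCatalog
#' @param catalog a [GwasCatalog-class].
#' @export
writeGwasCatalog <- function(catalog, path) {
  data.table::fwrite(catalogRecords(catalog), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a survival table (sample, time, event)
#'
#' Rows with missing time or event are dropped with a message reporting the
#' count.
#'
#' @param path TSV with header columns sample, time, event.
#' @return data.frame(sample, time, event).
#' @export
readSurvivalTable <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  .assert(all(c("sample", "time", "event") %in% names(tab)),
          "survival table needs columns sample, time, event")
  ok <- complete.cases(tab[, c("time", "event")])
  if (any(!ok)) message("dropped ", sum(!ok), " survival record(s) with missing time/event")
  tab[ok, c("sample", "time", "event"), drop = FALSE]
}
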