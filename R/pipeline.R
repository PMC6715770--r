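# end-to-end orchestration: pleiotropy ranking -> eQTL scan -> survival ->
# LD expansion -> evidence table -> motif disruption, one TSV per stage.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

.as_granges_region <- function(x) {
  if (is(x, "GRanges")) return(x)
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
}

#' Run the full variant-to-function pipeline
#'
#' Executes, in order: GWAS pleiotropy ranking, the copy-number-adjusted
#' cis-eQTL scan at the tag SNP, the median-split log-rank survival test for
#' the designated gene, LD expansion of the tag, evidence-table construction,
#' and motif disruption for gated candidates.  Each stage writes one TSV into
#' `out_dir`, plus a parameter-echo run log (no timestamps: a fixed seed gives
#' byte-identical output across runs).  A failing stage aborts with the stage
#' name and the offending input.
#'
#' @param config a named list (or path to a JSON file of file-path inputs)
#'   with elements:
#' \describe{
#'   \item{tag}{tag SNP id (required).}
#'   \item{simulate}{optional list of [simConfig()] arguments; when present
#'     the panel and cohort are simulated.  Sub-elements `gwas_clusters`
#'     (cluster spec for [simulateGwasCatalog()]) and `planted_motif`
#'     (`list(candidate, pwm_index)`, generates allele sequences with
#'     [plantMotifSnp()]) feed the other stages.}
#'   \item{inputs}{optional list of file paths: haplotypes, catalog,
#'     expression, dosage, cn, survival, genes, peaks (named), h3k4me1,
#'     interactions, pwms.}
#'   \item{query_category, neighbor_category}{pleiotropy categories
#'     (stage skipped when absent).}
#'   \item{surv_gene}{gene for the survival split (default: the eQTL gene
#'     with the smallest genotype p).}
#'   \item{peaks, h3k4me1, interactions, target, pwms, sequences}{in-memory
#'     objects overriding/complementing `inputs`; `target` may be a GRanges
#'     or `list(chrom, start, end)` (1-based).}
#'   \item{r2_min, maf_min, ld_window, cis_window, min_mean,
#'     proximity_window, fimo_threshold, n_sim, motif_gate}{thresholds; the
#'     defaults are 0.8, 0.05, 1e6, 1.5e6, 1, 1e5, 1e-3, 1000, TRUE.}
#'   \item{seed}{seed echoed to motif resampling (default 1).}
#' }
#' @param out_dir output directory, created if needed.
#' @return (invisibly) a list with the per-stage results: pleiotropy, eqtl,
#'   survival, ld, evidence.
#' @export
runPipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  .assert(!is.null(config$tag), "config must name the tag SNP ('tag')")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  ins <- config$inputs %||% list()
  log <- c("snp2target pipeline run",
           paste0("package version: ", as.character(utils::packageVersion("snp2target"))),
           paste0("seed: ", seed), paste0("tag: ", config$tag))

  # ---- assemble inputs (simulated or read from disk) ----
  panel <- cohort <- catalog <- NULL
  pwms <- config$pwms %||% list()
  sequences <- config$sequences %||% list()
  if (!is.null(config$simulate)) {
    simargs <- config$simulate
    clusters <- simargs$gwas_clusters
    planted <- simargs$planted_motif
    simargs$gwas_clusters <- NULL; simargs$planted_motif <- NULL
    if (is.null(simargs$seed)) simargs$seed <- seed
    cfg <- .stage("simulate", do.call(simConfig, simargs))
    panel <- .stage("simulate", simulateHaplotypes(cfg))
    cohort <- .stage("simulate", simulateCohort(panel, cfg))
    if (!is.null(clusters))
      catalog <- .stage("simulate", simulateGwasCatalog(cfg, clusters))
    if (!is.null(planted) && length(pwms)) {
      pl <- plantMotifSnp(pwms[[planted$pwm_index %||% 1L]], seed = cfg@seed + 3L)
      sequences[[planted$candidate]] <- pl
      log <- c(log, paste0("planted motif sequences for ", planted$candidate,
                           " at offset ", pl$offset))
    }
  } else {
    if (!is.null(ins$haplotypes))
      panel <- .stage("inputs", readHaplotypes(ins$haplotypes,
                                               population = config$population))
    if (!is.null(ins$catalog))
      catalog <- .stage("inputs", readGwasCatalog(ins$catalog))
    if (!is.null(ins$expression)) {
      expr <- .stage("inputs", readTsvMatrix(ins$expression))
      dosage <- .stage("inputs", readTsvMatrix(ins$dosage))
      cn <- if (!is.null(ins$cn)) .stage("inputs", readTsvMatrix(ins$cn))
            else matrix(0, nrow(expr), ncol(expr),
                        dimnames = dimnames(expr))
      surv <- if (!is.null(ins$survival))
        .stage("inputs", readSurvivalTable(ins$survival))
        else data.frame(sample = colnames(expr), time = NA_real_, event = NA_integer_)
      genes <- if (!is.null(ins$genes))
        .stage("inputs", data.table::fread(ins$genes, data.table = FALSE))
        else data.frame(id = rownames(expr), chrom = NA_character_, tss = NA_integer_)
      cohort <- .stage("inputs", CohortData(dosage, cn, expr, surv, genes))
    }
  }
  peaks <- config$peaks %||%
    (if (!is.null(ins$peaks)) lapply(ins$peaks, readIntervals) else list())
  h3k4me1 <- config$h3k4me1 %||%
    (if (!is.null(ins$h3k4me1)) readIntervals(ins$h3k4me1) else NULL)
  interactions <- config$interactions %||%
    (if (!is.null(ins$interactions)) readInteractions(ins$interactions) else NULL)
  if (!length(pwms) && !is.null(ins$pwms)) pwms <- readPwm(ins$pwms)
  target <- if (!is.null(config$target)) .as_granges_region(config$target) else NULL
  .assert(!is.null(panel), "config provides no haplotype input ",
          "(simulate block or inputs$haplotypes)")

  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  results <- list()

  # ---- stage 1: pleiotropy ranking ----
  if (!is.null(catalog) && !is.null(config$query_category)) {
    results$pleiotropy <- .stage("pleiotropy",
      rankByProximity(catalog, config$query_category, config$neighbor_category,
                      window = config$proximity_window %||% 1e5))
    tsv(results$pleiotropy, "01_pleiotropy.tsv")
    log <- c(log, paste0("pleiotropy: ranked ", nrow(results$pleiotropy),
                         " query SNPs"))
  }

  # ---- stage 2: cis-eQTL scan ----
  v <- variantInfo(panel)
  kt <- match(config$tag, v$id)
  .assert(!is.na(kt), "tag '", config$tag, "' not in haplotype panel")
  tag_rec <- variantRecord(config$tag, v$chrom[kt], v$pos[kt], v$ref[kt],
                           v$alt[kt])
  results$eqtl <- .stage("eqtl", {
    .assert(!is.null(cohort), "no expression input for the eQTL stage")
    expr <- filterExpressed(exprMatrix(cohort), min_mean = config$min_mean %||% 1)
    gset <- cisGeneSet(geneInfo(cohort), tag_rec,
                       window = config$cis_window %||% 1.5e6)
    genes <- intersect(rownames(expr), gset$id)
    .assert(length(genes) > 0, "no expressed cis genes at the tag SNP")
    eqtlScan(cohort, tag_rec, genes)
  })
  tsv(results$eqtl, "02_eqtl.tsv")
  log <- c(log, paste0("eqtl: ", nrow(results$eqtl), " genes scanned"))

  # ---- stage 3: survival ----
  surv_gene <- config$surv_gene %||% results$eqtl$gene[1]
  results$survival <- .stage("survival", {
    st <- survivalTable(cohort)
    ok <- complete.cases(st[, c("time", "event")])
    st <- st[ok, , drop = FALSE]
    .assert(nrow(st) >= 2, "no usable survival records")
    e <- exprMatrix(cohort)[surv_gene, st$sample]
    st$group <- medianSplit(e)
    lr <- logrankTest(st)
    list(gene = surv_gene, table = st, logrank = lr)
  })
  tsv(data.frame(gene = surv_gene, chi2 = results$survival$logrank$chi2,
                 p = results$survival$logrank$p,
                 n_high = sum(results$survival$table$group == "high"),
                 n_low = sum(results$survival$table$group == "low")),
      "03_survival.tsv")
  tsv(kmCurve(results$survival$table, "high"), "03_km_high.tsv")
  tsv(kmCurve(results$survival$table, "low"), "03_km_low.tsv")
  log <- c(log, sprintf("survival: gene %s log-rank chi2 %.4f p %.4g",
                        surv_gene, results$survival$logrank$chi2,
                        results$survival$logrank$p))

  # ---- stages 4-6: LD expansion, evidence, motif ----
  results$ld <- .stage("ld", ldExpand(panel, config$tag,
    r2_min = config$r2_min %||% 0.8, maf_min = config$maf_min %||% 0.05,
    window = config$ld_window %||% 1e6))
  tsv(results$ld, "04_ld_expand.tsv")
  log <- c(log, paste0("ld: ", nrow(results$ld), " proxies (tag included)"))

  results$evidence <- .stage("evidence", buildEvidenceTable(panel, config$tag,
    peak_sets = peaks, h3k4me1 = h3k4me1, interactions = interactions,
    target = target, pwms = pwms, sequences = sequences,
    r2_min = config$r2_min %||% 0.8, maf_min = config$maf_min %||% 0.05,
    window = config$ld_window %||% 1e6,
    motif_gate = config$motif_gate %||% TRUE,
    fimo_threshold = config$fimo_threshold %||% 1e-3,
    n_sim = config$n_sim %||% 1000, seed = seed))
  tsv(results$evidence, "05_evidence.tsv")
  log <- c(log, paste0("evidence: ", nrow(results$evidence), " candidates; top ",
                       if (nrow(results$evidence)) results$evidence$variant[1] else "none"))

  mres <- attr(results$evidence, "motif_results")
  motif_rows <- NULL
  if (length(mres))
    motif_rows <- do.call(rbind, unlist(lapply(names(mres), function(id)
      lapply(mres[[id]], function(r)
        data.frame(variant = id, pwm = r$pwm, delta = r$delta,
                   p_empirical = r$p_empirical, n_sim = r$n_sim))),
      recursive = FALSE))
  if (is.null(motif_rows))
    motif_rows <- data.frame(variant = character(), pwm = character(),
                             delta = numeric(), p_empirical = numeric(),
                             n_sim = integer())
  tsv(motif_rows, "06_motif.tsv")
  log <- c(log, paste0("motif: ", nrow(motif_rows), " (variant, PWM) tests"))

  writeLines(log, file.path(out_dir, "run.log"))
  invisible(results)
}
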