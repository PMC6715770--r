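# proximity-based pleiotropy ranking of GWAS variants.

.check_category <- function(catalog, category) {
  known <- categoryLabels(catalog)
  if (!(category %in% known))
    stop("unknown category '", category, "'; known categories: ",
         paste(known, collapse = ", "), call. = FALSE)
}

#' Count catalog SNPs of a category proximal to a SNP
#'
#' Distinct catalog SNPs of `category` on the same chromosome with
#' `|pos - snp$pos| <= window` (inclusive at both boundaries), excluding any
#' record sharing the query's snp id.
#'
#' @param catalog a [GwasCatalog-class].
#' @param snp a [variantRecord()].
#' @param window half-width in bp (default 1e5, i.e. "within 100 kb").
#' @param category neighbor category label; must exist in the catalog.
#' @return integer count of distinct neighbor snp ids.
#' @export
countProximal <- function(catalog, snp, window = 1e5, category) {
  .assert(window > 0, "window must be positive")
  .check_category(catalog, category)
  r <- catalogRecords(catalog)
  hit <- r$category == category & r$chrom == snp$chrom &
         abs(r$pos - snp$pos) <= window & r$snp_id != snp$id
  length(unique(r$snp_id[hit]))
}

#' Rank query-category GWAS SNPs by proximal neighbor density
#'
#' One row per distinct query-category SNP with the count of distinct
#' neighbor-category SNPs within `window`, sorted by count descending with a
#' deterministic (chrom, pos, snp_id) tie-break.
#'
#' @inheritParams countProximal
#' @param query_category category of the SNPs being ranked.
#' @param neighbor_category category whose local density is counted.
#' @return data.frame(snp_id, chrom, pos, neighbor_count, neighbor_ids) with
#'   `neighbor_ids` a comma-separated id list.
#' @export
rankByProximity <- function(catalog, query_category, neighbor_category,
                            window = 1e5) {
  .check_category(catalog, query_category)
  .check_category(catalog, neighbor_category)
  r <- catalogRecords(catalog)
  q <- r[r$category == query_category, , drop = FALSE]
  q <- q[!duplicated(q$snp_id), , drop = FALSE]
  nb <- r[r$category == neighbor_category, , drop = FALSE]
  rows <- lapply(seq_len(nrow(q)), function(i) {
    hit <- nb$chrom == q$chrom[i] & abs(nb$pos - q$pos[i]) <= window &
           nb$snp_id != q$snp_id[i]
    ids <- sort(unique(nb$snp_id[hit]))
    data.frame(snp_id = q$snp_id[i], chrom = q$chrom[i], pos = q$pos[i],
               neighbor_count = length(ids),
               neighbor_ids = paste(ids, collapse = ","))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$neighbor_count, out$chrom, out$pos, out$snp_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
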