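#' Monthly leaching risk index
#'
#' Leaching risk = leaching transport fraction x the sum of leachable N
#' sources (urine, dung, dairy effluent, fertilizer, belowground residues,
#' cultivation mineralization). Dimensionless; linear in every source.
#'
#' @param sources a [monthly_sources()] table (or any data.frame with the
#'   source columns), one row per month.
#' @param leach_risk leaching transport fraction(s) in \[0, 1\], recycled
#'   against the rows of `sources`.
#' @return numeric vector of leaching index values, one per row.
#' @export
leaching_index <- function(sources, leach_risk) {
  .check_sources(sources)
  if (any(leach_risk < 0 | leach_risk > 1)) {
    stop("leach_risk must lie in [0, 1]")
  }
  leach_risk * (sources$urine_n + sources$dung_n + sources$effluent_n +
                  sources$fert_n + sources$residue_bg_n + sources$cultivation_n)
}

#' Monthly runoff risk index
#'
#' Runoff risk = runoff transport fraction x the sum of runoff-available N
#' sources (erosion-borne soil N, dung, fertilizer, aboveground residues).
#' Urine is excluded: it is washed into the soil and unavailable to runoff.
#' Belowground residues and cultivation mineralization are likewise
#' leaching-only terms.
#'
#' @inheritParams leaching_index
#' @param runoff_risk runoff transport fraction(s) in \[0, 1\].
#' @param leach_risk leaching transport fraction(s); only consulted when
#'   `literal_eq2 = TRUE`.
#' @param literal_eq2 if `TRUE`, reproduce an alternative form of the
#'   runoff equation in which the dung, fertilizer and aboveground-residue
#'   terms are weighted by the *leaching* fraction (the erosion term keeps
#'   the runoff fraction in both modes). The default weights every term by
#'   the runoff fraction, consistent with the source-by-pathway structure.
#' @return numeric vector of runoff index values, one per row.
#' @export
runoff_index <- function(sources, runoff_risk, leach_risk = NULL,
                         literal_eq2 = FALSE) {
  .check_sources(sources)
  if (any(runoff_risk < 0 | runoff_risk > 1)) {
    stop("runoff_risk must lie in [0, 1]")
  }
  if (literal_eq2) {
    if (is.null(leach_risk)) {
      stop("literal_eq2 = TRUE requires leach_risk")
    }
    runoff_risk * sources$erosion_n +
      leach_risk * (sources$dung_n + sources$fert_n + sources$residue_ag_n)
  } else {
    runoff_risk * (sources$erosion_n + sources$dung_n + sources$fert_n +
                     sources$residue_ag_n)
  }
}

#' Score blocks: baseline monthly risk per block
#'
#' Joins each block's monthly source table to its transport risks and
#' computes the leaching and runoff indices and their total.
#'
#' @param blocks data.frame with columns `block_id`, `area_ha`, `land_use`,
#'   `location_id` (foreign key into the transport table), and optionally
#'   `soil_id`, `slope`, `irrigated`.
#' @param sources named list of [monthly_sources()] tables, one per
#'   `block_id`.
#' @param transport a [build_transport_table()] result.
#' @param literal_eq2 passed to [runoff_index()].
#' @return data.frame of class `risk_scores`: `block_id`, `month`,
#'   `leach_risk`, `runoff_risk`, `leach_index`, `runoff_index`, `total`.
#' @export
risk_scores <- function(blocks, sources, transport, literal_eq2 = FALSE) {
  missing_src <- setdiff(blocks$block_id, names(sources))
  if (length(missing_src) > 0) {
    stop("no source table for block(s): ", paste(missing_src, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    tr <- transport[transport$location_id == b$location_id, ]
    if (nrow(tr) != 12) {
      stop("transport table has ", nrow(tr), " rows for location '",
           b$location_id, "' (block '", b$block_id, "'); expected 12")
    }
    tr <- tr[order(tr$month), ]
    src <- sources[[as.character(b$block_id)]]
    src <- src[order(src$month), ]
    li <- leaching_index(src, tr$leach_risk)
    ri <- runoff_index(src, tr$runoff_risk, leach_risk = tr$leach_risk,
                       literal_eq2 = literal_eq2)
    data.frame(block_id = b$block_id, month = 1:12,
               leach_risk = tr$leach_risk, runoff_risk = tr$runoff_risk,
               leach_index = li, runoff_index = ri, total = li + ri)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("risk_scores", "data.frame")
  out
}

#' Aggregate block-month risk scores
#'
#' @param scores a [risk_scores()] data.frame (block-month rows).
#' @param mode `"annual"` (sum over months per block), `"farm"`
#'   (area-weighted mean of block annual totals) or `"pathway_shares"`
#'   (leaching and runoff shares of total risk).
#' @param blocks required for `mode = "farm"`: data.frame with `block_id`
#'   and `area_ha`.
#' @param year_basis `"calendar"` or `"hydrological"` (September--August).
#'   Only consulted when `scores` carries a `year` column; the hydrological
#'   basis assigns September--December to the following year's score.
#' @return `"annual"`: data.frame of per-block (per-year) sums;
#'   `"farm"`: one row per year with area-weighted `leach_index`,
#'   `runoff_index`, `total`; `"pathway_shares"`: one row with
#'   `leach_share`, `runoff_share` (summing to 1 when total > 0).
#' @export
aggregate_risk <- function(scores, mode = c("annual", "farm", "pathway_shares"),
                           blocks = NULL,
                           year_basis = c("calendar", "hydrological")) {
  mode <- match.arg(mode)
  year_basis <- match.arg(year_basis)
  if (nrow(scores) == 0) stop("scores must be non-empty")
  if ("year" %in% names(scores)) {
    yr <- scores$year
    if (year_basis == "hydrological") yr <- yr + (scores$month >= 9)
  } else {
    yr <- rep(1L, nrow(scores))
  }
  if (mode == "pathway_shares") {
    lt <- sum(scores$leach_index)
    rt <- sum(scores$runoff_index)
    tot <- lt + rt
    if (tot <= 0) {
      return(data.frame(leach_share = NA_real_, runoff_share = NA_real_))
    }
    return(data.frame(leach_share = lt / tot, runoff_share = rt / tot))
  }
  agg <- aggregate(scores[, c("leach_index", "runoff_index", "total")],
                   by = list(block_id = scores$block_id, year = yr), FUN = sum)
  if (mode == "annual") return(agg[order(agg$year, agg$block_id), ])
  # farm: area-weighted mean of block annual totals
  if (is.null(blocks)) stop("mode = 'farm' requires the blocks table for areas")
  idx <- match(agg$block_id, blocks$block_id)
  if (anyNA(idx)) {
    stop("blocks table missing area for block(s): ",
         paste(unique(agg$block_id[is.na(idx)]), collapse = ", "))
  }
  w <- blocks$area_ha[idx]
  out <- do.call(rbind, lapply(split(seq_len(nrow(agg)), agg$year), function(j) {
    data.frame(year = agg$year[j[1]],
               leach_index = sum(agg$leach_index[j] * w[j]) / sum(w[j]),
               runoff_index = sum(agg$runoff_index[j] * w[j]) / sum(w[j]),
               total = sum(agg$total[j] * w[j]) / sum(w[j]))
  }))
  rownames(out) <- NULL
  out
}
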