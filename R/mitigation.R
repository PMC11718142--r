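#' Define a source-changing mitigation (delta)
#'
#' A source delta changes a baseline N source by a fractional amount before
#' the risk index is recomputed (for example, destocking lowers urine and
#' dung inputs).
#'
#' @param category a source column name (see [monthly_sources()]).
#' @param delta fractional change in \[-1, Inf); the category is scaled by
#'   `1 + delta`, floored at zero.
#' @param land_uses land uses the delta applies to (`NULL` = all).
#' @param months calendar months the delta applies to (`NULL` = all).
#' @return list of class `source_delta`.
#' @export
source_delta <- function(category, delta, land_uses = NULL, months = NULL) {
  if (!category %in% .source_categories) {
    stop("unknown source category '", category, "'; expected one of ",
         paste(.source_categories, collapse = ", "))
  }
  if (delta < -1) stop("delta must be >= -1 (cannot remove more than all of a source)")
  if (!is.null(months) && !all(months %in% 1:12)) stop("months must be in 1..12")
  structure(list(category = category, delta = delta,
                 land_uses = land_uses, months = months),
            class = "source_delta")
}

#' Apply source deltas to a monthly source table
#'
#' Deltas are applied in sequence; two deltas on the same category compose
#' multiplicatively. Deltas whose land-use filter does not match are dropped
#' with a warning, not an error.
#'
#' @param sources a [monthly_sources()] table.
#' @param deltas list of [source_delta()] objects.
#' @param land_use the block's land use, checked against each delta's filter.
#' @return the adjusted [monthly_sources()] table.
#' @export
apply_source_deltas <- function(sources, deltas, land_use = NULL) {
  .check_sources(sources)
  for (d in deltas) {
    stopifnot(inherits(d, "source_delta"))
    if (!is.null(d$land_uses) && !is.null(land_use) &&
        !land_use %in% d$land_uses) {
      warning("delta on '", d$category, "' does not apply to land use '",
              land_use, "'; skipped")
      next
    }
    rows <- if (is.null(d$months)) 1:12 else sources$month %in% d$months
    sources[rows, d$category] <- pmax(0, sources[rows, d$category] * (1 + d$delta))
  }
  sources
}

#' Define a risk modifier
#'
#' A modifier is a mitigation (such as a wetland or denitrification bed)
#' that does not change sources but multiplies the computed pathway risk by
#' `1 - effectiveness`. Base effectiveness can be adjusted for the block's
#' climate, slope and soil class through named factor tables (default 1,
#' i.e. no adjustment); the adjusted effectiveness must remain in \[0, 1\].
#'
#' @param name modifier name (used to break effectiveness ties
#'   deterministically).
#' @param pathway `"leaching"`, `"runoff"` or `"both"`.
#' @param effectiveness base effectiveness e in \[0, 1\].
#' @param land_uses land uses the modifier applies to (`NULL` = all).
#' @param climate_adj,slope_adj,soil_adj named numeric lookup vectors of
#'   multiplicative adjustment factors by class; classes absent from a table
#'   default to 1.
#' @return list of class `risk_modifier`.
#' @export
risk_modifier <- function(name, pathway = c("both", "leaching", "runoff"),
                          effectiveness, land_uses = NULL,
                          climate_adj = NULL, slope_adj = NULL,
                          soil_adj = NULL) {
  pathway <- match.arg(pathway)
  if (effectiveness < 0 || effectiveness > 1) {
    stop("base effectiveness must lie in [0, 1]")
  }
  structure(list(name = name, pathway = pathway,
                 effectiveness = effectiveness, land_uses = land_uses,
                 climate_adj = climate_adj, slope_adj = slope_adj,
                 soil_adj = soil_adj),
            class = "risk_modifier")
}

.lookup_adj <- function(table, class) {
  if (is.null(table) || is.null(class) || !class %in% names(table)) return(1)
  table[[class]]
}

#' Adjusted effectiveness of a modifier in a block context
#'
#' @param modifier a [risk_modifier()].
#' @param context list with optional `climate_class`, `slope_class`,
#'   `soil_class`.
#' @return adjusted effectiveness in \[0, 1\]; values outside are an error.
#' @export
adjusted_effectiveness <- function(modifier, context = list()) {
  e <- modifier$effectiveness *
    .lookup_adj(modifier$climate_adj, context$climate_class) *
    .lookup_adj(modifier$slope_adj, context$slope_class) *
    .lookup_adj(modifier$soil_adj, context$soil_class)
  if (e < 0 || e > 1) {
    stop("adjusted effectiveness of modifier '", modifier$name, "' is ",
         signif(e, 4), "; must lie in [0, 1]")
  }
  e
}

#' Apply modifiers to a baseline risk score
#'
#' Modifiers are filtered to the block's land use, sorted by adjusted
#' effectiveness from most to least effective (ties broken by name), and
#' applied in series: each step multiplies the running pathway score by
#' `1 - effectiveness`, so each later modifier acts on the product left by
#' the previous one. The final score equals baseline x the product of
#' `(1 - e_i)` and is therefore independent of input order; the ordering
#' governs the audit trail, which mirrors the diminishing returns of
#' stacking mitigations. Modifiers are assumed optimally placed to intercept
#' their pathway; no placement model or modifier interaction is applied.
#'
#' @param score baseline risk, a named numeric vector
#'   `c(leaching = , runoff = )` (a bare scalar is taken as a runoff-and-
#'   leaching total only when exactly one pathway is targeted by the
#'   modifiers; prefer the named form).
#' @param modifiers list of [risk_modifier()] objects.
#' @param context list with optional `land_use`, `climate_class`,
#'   `slope_class`, `soil_class`.
#' @return list of class `mitigated_risk`: `baseline`, `final` (both named
#'   vectors with `leaching`, `runoff` and `total`), and `audit`, a
#'   data.frame with one row per applied step (`step`, `modifier`,
#'   `pathway`, `effectiveness`, `leaching`, `runoff`, `total` after the
#'   step), preceded by a step-0 baseline row.
#' @export
apply_modifiers <- function(score, modifiers, context = list()) {
  if (is.null(names(score))) {
    if (length(score) != 1) stop("score must be named c(leaching=, runoff=) or a scalar")
    paths <- unique(vapply(modifiers, function(m) m$pathway, character(1)))
    paths <- setdiff(paths, "both")
    if (length(paths) > 1) {
      stop("a bare scalar score is ambiguous with modifiers on both pathways; ",
           "use c(leaching = , runoff = )")
    }
    target <- if (length(paths) == 1) paths else "leaching"
    val <- score
    score <- c(leaching = 0, runoff = 0)
    score[target] <- val
  }
  if (!all(c("leaching", "runoff") %in% names(score))) {
    stop("score must have elements 'leaching' and 'runoff'")
  }
  if (any(score < 0)) stop("baseline scores must be >= 0")
  lu <- context$land_use
  keep <- vapply(modifiers, function(m) {
    is.null(m$land_uses) || is.null(lu) || lu %in% m$land_uses
  }, logical(1))
  modifiers <- modifiers[keep]
  e_adj <- vapply(modifiers, adjusted_effectiveness, numeric(1),
                  context = context)
  nm <- vapply(modifiers, function(m) m$name, character(1))
  ord <- order(-e_adj, nm) # most effective first, ties by name
  modifiers <- modifiers[ord]
  e_adj <- e_adj[ord]

  cur <- score[c("leaching", "runoff")]
  audit <- data.frame(step = 0L, modifier = "(baseline)", pathway = "",
                      effectiveness = NA_real_,
                      leaching = cur[["leaching"]], runoff = cur[["runoff"]],
                      total = sum(cur))
  for (i in seq_along(modifiers)) {
    m <- modifiers[[i]]
    p <- if (m$pathway == "both") c("leaching", "runoff") else m$pathway
    cur[p] <- cur[p] * (1 - e_adj[i])
    audit <- rbind(audit, data.frame(
      step = i, modifier = m$name, pathway = m$pathway,
      effectiveness = e_adj[i],
      leaching = cur[["leaching"]], runoff = cur[["runoff"]],
      total = sum(cur)))
  }
  structure(
    list(baseline = c(score[c("leaching", "runoff")], total = sum(score[c("leaching", "runoff")])),
         final = c(cur, total = sum(cur)),
         audit = audit),
    class = "mitigated_risk"
  )
}

#' @export
print.mitigated_risk <- function(x, ...) {
  cat("Mitigated risk score\n")
  cat(sprintf("  baseline: leaching %.3f, runoff %.3f (total %.3f)\n",
              x$baseline[["leaching"]], x$baseline[["runoff"]],
              x$baseline[["total"]]))
  cat(sprintf("  final:    leaching %.3f, runoff %.3f (total %.3f)\n",
              x$final[["leaching"]], x$final[["runoff"]], x$final[["total"]]))
  cat("  steps (most to least effective):\n")
  steps <- x$audit[x$audit$step > 0, ]
  for (i in seq_len(nrow(steps))) {
    cat(sprintf("   %d. %s [%s, e = %.3f] -> total %.3f\n", steps$step[i],
                steps$modifier[i], steps$pathway[i], steps$effectiveness[i],
                steps$total[i]))
  }
  invisible(x)
}
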