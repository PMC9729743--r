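#' Balance and stability of the IVC flow split
#'
#' The reference split of IVC flow between left and right pulmonary artery is
#' 45/55 (LPA/RPA). `imbalance` is the mean absolute deviation of LPA% from
#' the reference across exercise levels; `instability` is the range
#' (max - min) of LPA% across levels.
#'
#' @param lpa_pct numeric vector of LPA percentages, one per exercise level,
#'   or a two-column matrix/data.frame of (LPA, RPA) percentages.
#' @param reference reference LPA percentage (default 45).
#' @return list with `imbalance` and `instability` (percentage points).
#' @examples
#' balance_index(c(60, 48.2, 46.4, 47))$instability  # 13.6
#' @export
balance_index <- function(lpa_pct, reference = 45) {
  if (is.matrix(lpa_pct) || is.data.frame(lpa_pct)) {
    m <- as.matrix(lpa_pct)
    if (ncol(m) != 2) validation_error("expected two columns (LPA, RPA)")
    if (any(abs(rowSums(m) - 100) > 1e-6))
      validation_error("LPA% + RPA% must equal 100 at every level")
    lpa_pct <- m[, 1]
  }
  if (length(lpa_pct) < 1) validation_error("need at least one level")
  list(imbalance = mean(abs(lpa_pct - reference)),
       instability = max(lpa_pct) - min(lpa_pct))
}

#' Assemble the per-design indicator table
#'
#' One row per design with the four scored indicators, aggregated over
#' exercise levels by their mean: pressure gradient (mmHg), conduit section
#' velocity (m/s), energy efficiency (fraction) and flow-split imbalance
#' (mean |LPA% - 45|). Instability (range of LPA%) is carried along for
#' reporting but not scored.
#'
#' @param reports a data.frame of [hemodynamic_report()] rows covering every
#'   design at every level.
#' @param reference reference LPA percentage.
#' @return an `indicator_table` data.frame keyed by design.
#' @export
indicator_table <- function(reports, reference = 45) {
  if (length(unique(table(reports$design, reports$level))) > 1 ||
      any(table(reports$design, reports$level) != 1))
    validation_error("every design needs exactly one report per level")
  designs <- unique(reports$design)
  rows <- lapply(designs, function(dg) {
    r <- reports[reports$design == dg, ]
    bal <- if (all(is.na(r$lpa_pct))) list(imbalance = NA_real_,
                                           instability = NA_real_)
           else balance_index(r$lpa_pct, reference)
    data.frame(design = dg,
               pg = mean(r$pg_mmhg),
               velocity = mean(r$section_velocity_ms),
               efficiency = mean(r$efficiency),
               balance = bal$imbalance,
               instability = bal$instability,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("indicator_table", "data.frame")
  out
}

#' Rank designs on the four indicators and score 4/3/2/1
#'
#' Within each indicator the best design scores 4 points, the next 3, then 2,
#' then 1 (ties receive the mean of the tied scores). Lower is better for
#' pressure gradient, section velocity and flow-split imbalance; higher is
#' better for efficiency. With four designs the scores in each indicator sum
#' to 10 and the totals over all designs to 40.
#'
#' @param table an [indicator_table()] (or data.frame with columns `design`,
#'   `pg`, `velocity`, `efficiency`, `balance`).
#' @param directions named character vector, `"lower"`/`"higher"` is better,
#'   per indicator.
#' @return an object of class `score_card`: per-indicator scores, totals and
#'   the selected design.
#' @examples
#' tab <- data.frame(design = c("A", "B", "C", "D"),
#'                   pg = c(3, 4, 2, 1), velocity = c(1, 4, 3, 2),
#'                   efficiency = c(2, 1, 3, 4), balance = c(4, 1, 2, 3))
#' rank_and_score(tab)$totals
#' @export
rank_and_score <- function(table,
                           directions = c(pg = "lower", velocity = "lower",
                                          efficiency = "higher",
                                          balance = "lower")) {
  missing <- setdiff(names(directions), names(table))
  if (length(missing))
    validation_error(sprintf("indicator table is missing: %s",
                             paste(missing, collapse = ", ")))
  if (nrow(table) < 2) validation_error("need at least two designs to rank")
  n <- nrow(table)
  scores <- sapply(names(directions), function(ind) {
    v <- table[[ind]]
    if (directions[[ind]] == "higher") v <- -v
    (n + 1) - rank(v, ties.method = "average")
  })
  rownames(scores) <- table$design
  totals <- rowSums(scores)
  structure(list(scores = scores, totals = totals,
                 indicators = table,
                 selected = select_label(totals, table)),
            class = "score_card")
}

select_label <- function(totals, table) {
  best <- names(totals)[totals == max(totals)]
  if (length(best) > 1) {
    # tie on totals: prefer the lower pressure gradient
    pg <- setNames(table$pg, table$design)[best]
    best <- best[which.min(pg)]
  }
  best
}

#' Pick the winning design from a score card
#'
#' The design with the highest total; ties are broken towards the lower
#' pressure gradient.
#'
#' @param card a [rank_and_score()] score card.
#' @return the selected design label.
#' @export
select_best <- function(card) {
  if (!inherits(card, "score_card") || length(card$totals) == 0)
    validation_error("empty or invalid score card")
  card$selected
}

#' @export
print.score_card <- function(x, ...) {
  cat("<score_card>\n")
  m <- cbind(x$scores, total = x$totals)
  print(round(m, 2))
  cat("selected design:", x$selected, "\n")
  invisible(x)
}

#' Left/right lung totals from regional perfusion percentages
#'
#' Sums regional (upper/middle/lower) perfusion percentages per lung — the
#' arithmetic used to read a postoperative radionuclide perfusion scan as an
#' IVC flow split.
#'
#' @param regions data.frame with columns `left` and `right`, one row per
#'   lung region; percentages over both lungs sum to 100.
#' @return named numeric vector with `left` and `right` totals.
#' @examples
#' scan <- data.frame(region = c("upper", "middle", "lower"),
#'                    left = c(8.1, 21.79, 16.82),
#'                    right = c(9.66, 25.97, 17.66))
#' perfusion_totals(scan)  # left 46.71, right 53.29
#' @export
perfusion_totals <- function(regions) {
  if (!all(c("left", "right") %in% names(regions)))
    validation_error("regions must have 'left' and 'right' columns")
  c(left = sum(regions$left), right = sum(regions$right))
}
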