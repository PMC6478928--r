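#' Map p-values to significance codes
#'
#' Thresholds 0.001, 0.01, 0.05 and 0.1 give `***`, `**`, `*`, `.` and
#' `n.s.`.
#'
#' @param p numeric p-values.
#' @return character codes.
#' @export
signif_code <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
      labels = c("***", "**", "*", ".", "n.s."), right = FALSE) |>
    as.character()
}

# Translate a design-term name into a model-formula term. `data` may gain an
# orientation matrix column (sin, cos of the aspect in degrees), encoding the
# circular variable with 2 df.
.term_map <- c(BGR = "region", MI = "mi", TI = "ti",
               "MI:TI" = "mi:ti", "TI:MI" = "ti:mi",
               PCo1 = "pco1", PCo2 = "pco2",
               pH = "ph", Clay = "clay", Slope = "slope",
               Orientation = "orientation_circ")

.resolve_terms <- function(data, terms) {
  out <- character(length(terms))
  for (i in seq_along(terms)) {
    tm <- terms[i]
    out[i] <- if (tm %in% names(.term_map)) .term_map[[tm]] else tm
  }
  if ("orientation_circ" %in% out && !"orientation_circ" %in% names(data)) {
    if (!"orientation_deg" %in% names(data))
      stop("orientation term requested but `orientation_deg` column missing")
    th <- data$orientation_deg * pi / 180
    data$orientation_circ <- cbind(sin = sin(th), cos = cos(th))
  }
  # an interaction must not precede both of its main effects
  for (i in seq_along(out)) {
    parts <- strsplit(out[i], ":", fixed = TRUE)[[1L]]
    if (length(parts) == 2L && !any(parts %in% out[seq_len(i - 1L)]))
      stop("interaction term `", terms[i],
           "` precedes both of its main effects")
  }
  list(data = data, terms = out)
}

.response_map <- c(log_tau14c = "log(tau_14c)", log_taui = "log(tau_i)",
                   doc = "doc")

.resolve_response <- function(response) {
  if (response %in% names(.response_map)) .response_map[[response]]
  else response
}

#' Default site exclusions per response
#'
#' Incubation-turnover analyses drop sites whose NaOH traps saturated and
#' sites flagged by residual diagnostics; radiocarbon-turnover analyses drop
#' sites with unrealistic turnover (e.g. accidental sampling below 20 cm);
#' DOC analyses drop saturated sites only.
#'
#' @param data data frame with a `site_id` column; a logical `saturated`
#'   column, if present, contributes exclusions for `log_taui` and `doc`.
#' @param response one of `"log_taui"`, `"log_tau14c"`, `"doc"`.
#' @param exclusions named list of site-id vectors overriding the defaults
#'   (defaults: `log_taui` = 6, 12, 24; `log_tau14c` = 40; `doc` = none).
#' @param quiet suppress the exclusion log message.
#' @return the filtered data frame; excluded ids are attached as
#'   `attr(, "excluded")`.
#' @export
apply_exclusions <- function(data, response,
                             exclusions = list(log_taui = c("6", "12", "24"),
                                               log_tau14c = "40",
                                               doc = character(0)),
                             quiet = FALSE) {
  stopifnot(is.data.frame(data), "site_id" %in% names(data))
  ids <- as.character(data$site_id)
  drop <- as.character(exclusions[[response]] %||% character(0))
  if ("saturated" %in% names(data) && response %in% c("log_taui", "doc"))
    drop <- union(drop, ids[data$saturated %in% TRUE])
  drop <- intersect(drop, ids)
  if (length(drop) && !quiet)
    message("excluding ", length(drop), " site(s) for ", response, ": ",
            paste(drop, collapse = ", "))
  out <- data[!ids %in% drop, , drop = FALSE]
  attr(out, "excluded") <- drop
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Blocked sequential (Type-I) ANOVA
#'
#' Fits a multiple linear regression with terms entered in the given order
#' and summarises it by a sequential analysis of variance: each term's sum of
#' squares is the reduction in residual SS when it is added after all
#' preceding terms. The biogeographical region enters as a blocking factor by
#' listing it first. Categorical variables use treatment contrasts;
#' orientation in degrees is encoded as a two-column (sin, cos) term.
#'
#' @param data data frame holding the response and design columns
#'   (`region`, `mi`, `ti`, `pco1`, `pco2`, drivers, ...).
#' @param response `"log_tau14c"`, `"log_taui"`, `"doc"`, or any expression
#'   of columns in `data`.
#' @param terms ordered character vector of design terms; recognised names
#'   are `BGR`, `MI`, `TI`, `MI:TI`, `TI:MI`, `PCo1`, `PCo2`, `pH`, `Clay`,
#'   `Slope`, `Orientation`, or raw column names.
#' @return a data frame of class `anova_table` with one row per term plus a
#'   `Residuals` row: `term`, `df`, `ss`, `ms`, `f`, `p`, `code`.
#' @examples
#' \dontrun{
#' sequential_anova(d, "log_taui", c("BGR", "MI", "TI", "MI:TI",
#'                                   "PCo1", "PCo2"))
#' }
#' @export
sequential_anova <- function(data, response, terms) {
  stopifnot(is.data.frame(data), length(terms) >= 1L)
  rt <- .resolve_terms(data, terms)
  fml <- stats::as.formula(
    paste(.resolve_response(response), "~", paste(rt$terms, collapse = " + ")))
  tt <- stats::terms(fml, keep.order = TRUE)
  fit <- stats::lm(tt, data = rt$data)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design: collinear term(s) ",
         paste(unique(bad), collapse = ", "))
  }
  if (stats::df.residual(fit) <= 0)
    stop("no residual degrees of freedom: n too small for the model")
  a <- stats::anova(fit)
  out <- data.frame(term = rownames(a), df = a$Df, ss = a$`Sum Sq`,
                    ms = a$`Mean Sq`, f = a$`F value`, p = a$`Pr(>F)`,
                    row.names = NULL)
  out$code <- ifelse(out$term == "Residuals", "", signif_code(out$p))
  # report rows under the design-term names used by the caller
  lab <- terms[match(out$term, rt$terms)]
  out$term <- ifelse(is.na(lab), out$term, lab)
  attr(out, "response") <- response
  attr(out, "n") <- stats::nobs(fit)
  attr(out, "total_ss") <- sum(out$ss)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Order-permutation consistency screening
#'
#' Runs the sequential ANOVA under several term orderings of the same model
#' and screens each driver: a driver counts as significant only if p < 0.05
#' in every ordering; significance in some orderings but not others is marked
#' `crossed_out` (not meaningful — it depends on where the driver enters the
#' sequential decomposition); otherwise `n.s.`.
#'
#' @param data data frame as in [sequential_anova()].
#' @param response response name.
#' @param orderings named list of at least two term-order vectors; all must
#'   contain the same set of terms.
#' @param drivers terms to screen (default: all shared non-residual terms).
#' @return a list of class `consistency_report`: `tables` (one
#'   [sequential_anova()] table per ordering), `drivers` (data frame with
#'   per-ordering p-values and codes plus the `verdict`).
#' @export
order_consistency <- function(data, response, orderings, drivers = NULL) {
  if (!is.list(orderings) || length(orderings) < 2L)
    stop("need at least two orderings to screen consistency")
  canon <- function(v) sort(sub("TI:MI", "MI:TI", v, fixed = TRUE))
  base <- canon(orderings[[1L]])
  for (o in orderings[-1L])
    if (!identical(canon(o), base))
      stop("orderings must share the same term set")
  if (is.null(names(orderings)))
    names(orderings) <- vapply(orderings, paste, "", collapse = " + ")
  tabs <- lapply(orderings, function(o) sequential_anova(data, response, o))
  if (is.null(drivers)) drivers <- setdiff(orderings[[1L]], NULL)
  norm <- function(v) sub("TI:MI", "MI:TI", v, fixed = TRUE)
  p_mat <- vapply(tabs, function(tb) {
    p <- tb$p[match(norm(drivers), norm(tb$term))]
    p
  }, numeric(length(drivers)))
  p_mat <- matrix(p_mat, nrow = length(drivers),
                  dimnames = list(drivers, names(orderings)))
  sig <- p_mat < 0.05
  verdict <- apply(sig, 1L, function(s) {
    if (all(s)) "significant" else if (any(s)) "crossed_out" else "n.s."
  })
  drv <- data.frame(driver = drivers, verdict = verdict, row.names = NULL)
  for (j in seq_len(ncol(p_mat))) {
    drv[[paste0("p.", colnames(p_mat)[j])]] <- p_mat[, j]
    drv[[paste0("code.", colnames(p_mat)[j])]] <- signif_code(p_mat[, j])
  }
  structure(list(tables = tabs, drivers = drv, response = response),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("Order-consistency report for", x$response, "(",
      length(x$tables), "orderings )\n")
  print(x$drivers[, c("driver", "verdict")], row.names = FALSE)
  invisible(x)
}

#' Pearson correlation summaries
#'
#' Pearson r with a two-sided t-test p-value for each requested variable
#' pair, on pairwise-complete observations.
#'
#' @param data data frame.
#' @param pairs list of 2-element character vectors naming columns of
#'   `data`.
#' @return data frame with `var1`, `var2`, `n`, `r`, `p`.
#' @export
pearson_summary <- function(data, pairs) {
  stopifnot(is.data.frame(data), is.list(pairs))
  rows <- lapply(pairs, function(pr) {
    x <- data[[pr[1L]]]; y <- data[[pr[2L]]]
    if (is.null(x) || is.null(y))
      stop("unknown variable in pair: ", paste(pr, collapse = ", "))
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L) stop("fewer than 3 complete pairs for ",
                           paste(pr, collapse = " vs "))
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      stop("zero variance in ", paste(pr, collapse = " or "))
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(var1 = pr[1L], var2 = pr[2L], n = sum(ok),
               r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, rows)
}

#' Standard model-structure orderings
#'
#' `table1_orderings()` returns the two climate-model orderings (region
#' block, then moisture-by-temperature entered in either order, then PCo1
#' and PCo2). `table2_orderings(driver)` returns the three positions of a
#' single soil/landform driver relative to the block and climate terms.
#'
#' @return named list of term-order vectors for [order_consistency()].
#' @export
table1_orderings <- function() {
  list("BGR + MI x TI + PCo1 + PCo2" =
         c("BGR", "MI", "TI", "MI:TI", "PCo1", "PCo2"),
       "BGR + TI x MI + PCo1 + PCo2" =
         c("BGR", "TI", "MI", "TI:MI", "PCo1", "PCo2"))
}

#' @rdname table1_orderings
#' @param driver driver term name (`"pH"`, `"Clay"`, `"Slope"`,
#'   `"Orientation"` or a column name).
#' @export
table2_orderings <- function(driver) {
  stats::setNames(
    list(c(driver, "BGR", "MI", "TI", "MI:TI"),
         c("BGR", driver, "MI", "TI", "MI:TI"),
         c("BGR", "MI", "TI", "MI:TI", driver)),
    c(paste(driver, "+ BGR + MI x TI"),
      paste("BGR +", driver, "+ MI x TI"),
      paste("BGR + MI x TI +", driver)))
}
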