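#' Filter a candidate-site population by slope
#'
#' Removes sites on slopes steeper than `slope_max` percent, so that erosion
#' losses can be assumed negligible relative to mineralisation — except
#' long-term monitoring (LWF) sites, which are retained regardless of slope.
#' The comparison is strict: a slope exactly at the threshold is kept.
#'
#' @param sites data frame with at least `slope` (%); an optional logical
#'   `is_lwf` column marks long-term monitoring sites.
#' @param slope_max maximum slope in percent (default 50).
#' @return the filtered data frame.
#' @export
filter_population <- function(sites, slope_max = 50) {
  stopifnot(is.data.frame(sites), "slope" %in% names(sites))
  lwf <- if ("is_lwf" %in% names(sites)) sites$is_lwf else FALSE
  sites[sites$slope <= slope_max | lwf, , drop = FALSE]
}

#' Dryness index: count of dry months
#'
#' A month is dry when its precipitation is strictly smaller than its
#' potential evapotranspiration (PET, supplied as an input, e.g. Penman).
#' The cumulative count of dry months over the climate-normal period is the
#' moisture proxy used to categorise sites: more dry months means a drier
#' site.
#'
#' @param monthly_p monthly precipitation, mm.
#' @param monthly_pet monthly potential evapotranspiration, mm, same length.
#' @return integer count of dry months.
#' @export
dryness_index <- function(monthly_p, monthly_pet) {
  if (length(monthly_p) != length(monthly_pet))
    stop("precipitation and PET series must have equal length")
  sum(monthly_p < monthly_pet)
}

#' Median-split climate categories
#'
#' Partitions sites into four equiprobable climate categories by the
#' population medians of temperature and dryness: TT+ (warm) vs TT- (cold),
#' and MI+ (moist, few dry months) vs MI- (dry). Sites exactly at a median
#' fall into the lower-covariate bin (TT- for temperature, MI+ for dryness,
#' since low dryness means moist).
#'
#' @param sites data frame with numeric `temp` and `dryness` columns.
#' @return `sites` with added factor columns `ti` (`TT-`/`TT+`), `mi`
#'   (`MI-`/`MI+`) and `climate_cat` (their interaction).
#' @export
climate_categories <- function(sites) {
  stopifnot(is.data.frame(sites), nrow(sites) >= 2L,
            all(c("temp", "dryness") %in% names(sites)))
  if (length(unique(sites$temp)) < 2L)
    stop("temperature is constant: no median split possible")
  if (length(unique(sites$dryness)) < 2L)
    stop("dryness is constant: no median split possible")
  med_t <- stats::median(sites$temp)
  med_d <- stats::median(sites$dryness)
  sites$ti <- factor(ifelse(sites$temp > med_t, "TT+", "TT-"),
                     levels = c("TT-", "TT+"))
  sites$mi <- factor(ifelse(sites$dryness > med_d, "MI-", "MI+"),
                     levels = c("MI-", "MI+"))
  sites$climate_cat <- interaction(sites$mi, sites$ti, sep = ":")
  sites
}

#' Principal coordinates of soil and landform covariates
#'
#' Reduces soil pH, clay content, slope and orientation to two orthogonal
#' axes (PCo1, PCo2) by principal coordinates analysis (classical metric
#' multidimensional scaling): a pairwise distance matrix is double-centred
#' and eigendecomposed, and sites are embedded so that Euclidean distances in
#' the plane approximate the original dissimilarities. The default Gower
#' distance range-scales numeric variables and uses simple matching for the
#' categorical orientation; `"euclidean_standardized"` uses Euclidean
#' distance on standardised numeric columns (in which case PCoA coincides
#' with PCA of the standardised matrix, up to axis sign).
#'
#' @param sites data frame containing `vars`.
#' @param vars variables to aggregate (default pH, clay, slope,
#'   orientation).
#' @param distance `"gower"` (default) or `"euclidean_standardized"`.
#' @return a list with `pco1`, `pco2` (coordinates scaled by the square root
#'   of their eigenvalues), `eigenvalues` (all, including any negative ones
#'   Gower can produce) and `points` (the full coordinate matrix on
#'   positive-eigenvalue axes).
#' @export
pcoa_soil_landform <- function(sites,
                               vars = c("ph", "clay", "slope", "orientation"),
                               distance = c("gower",
                                            "euclidean_standardized")) {
  distance <- match.arg(distance)
  stopifnot(is.data.frame(sites), nrow(sites) >= 3L)
  vars <- intersect(vars, names(sites))
  if (!length(vars)) stop("none of `vars` present in `sites`")
  x <- sites[, vars, drop = FALSE]
  if (distance == "gower") {
    for (v in vars) if (is.character(x[[v]])) x[[v]] <- factor(x[[v]])
    d <- cluster::daisy(x, metric = "gower", warnBin = FALSE,
                        warnAsym = FALSE, warnConst = FALSE)
  } else {
    num <- vapply(x, is.numeric, logical(1))
    if (!all(num))
      stop("euclidean_standardized distance needs numeric variables only")
    d <- stats::dist(scale(as.matrix(x)))
  }
  mds <- suppressWarnings(
    stats::cmdscale(d, k = min(nrow(sites) - 1L, length(vars) + 2L),
                    eig = TRUE))
  eig <- mds$eig
  tol <- sqrt(.Machine$double.eps) * max(abs(eig))
  n_pos <- sum(eig > tol)
  if (n_pos < 1L)
    stop("no positive eigenvalues: sites are indistinguishable under ",
         "the chosen distance")
  pts <- mds$points[, seq_len(min(n_pos, ncol(mds$points))), drop = FALSE]
  # a perfectly one-dimensional configuration embeds on a single axis; the
  # second coordinate is then identically zero
  pco2 <- if (ncol(pts) >= 2L) pts[, 2L] else rep(0, nrow(pts))
  list(pco1 = pts[, 1L], pco2 = pco2, eigenvalues = eig, points = pts)
}

# Greedy farthest-point subset of radii: pick sites whose distances to the
# PCo origin are maximally spread, deterministically (ties by site_id).
.pick_spread <- function(ids, radii, n_pick) {
  if (n_pick <= 0L) return(character(0))
  o <- order(radii, ids)
  ids <- ids[o]; radii <- radii[o]
  if (n_pick >= length(ids)) return(ids)
  chosen <- which.max(radii)           # start from the outermost site
  while (length(chosen) < n_pick) {
    gap <- vapply(seq_along(radii), function(i) {
      if (i %in% chosen) -Inf else min(abs(radii[i] - radii[chosen]))
    }, numeric(1))
    chosen <- c(chosen, which.max(gap))  # which.max: first index on ties
  }
  ids[sort(chosen)]
}

# Largest-remainder apportionment of `total` picks over cell `counts`,
# proportional to `weights`, capped by availability.
.apportion <- function(counts, weights, total) {
  q <- rep(0L, length(counts))
  remaining <- total
  while (remaining > 0L) {
    open <- counts > q & weights > 0
    if (!any(open)) break
    share <- weights * open / sum(weights[open])
    exact <- share * remaining
    add <- pmin(floor(exact), counts - q)
    if (sum(add) == 0L) {
      i <- order(exact - floor(exact), decreasing = TRUE)
      i <- i[open[i] & (counts - q)[i] > 0][1L]
      add[i] <- 1L
    }
    q <- q + add
    remaining <- total - sum(q)
  }
  q
}

#' Select a near-orthogonal site subset
#'
#' Implements the reproducible core of the stratified site selection: within
#' each biogeographical-region x climate-category cell, candidates are chosen
#' by a deterministic greedy criterion that spreads their distance-to-origin
#' in the PCo1-PCo2 plane (farthest-point selection on radii, ties broken by
#' site id). Picks are apportioned equally over the four climate categories
#' and, within a category, equally over the regions that have candidates;
#' empty or thin cells yield fewer picks with a warning, since some
#' climate-region combinations simply do not occur.
#'
#' @param sites data frame with `site_id`, `region`, `temp`, `dryness` and
#'   the PCoA input variables; categories and coordinates are computed here
#'   if absent.
#' @param n_target number of sites to select (default 54).
#' @param distance passed to [pcoa_soil_landform()].
#' @return a list of class `design_selection` with `selected` (site ids),
#'   `sites` (the annotated population with `selected` flag, `ti`, `mi`,
#'   `pco1`, `pco2`), `orthogonality_report` (max absolute pairwise
#'   correlation among temperature and moisture categories, PCo1, PCo2 and
#'   region dummies — dummy-vs-dummy pairs excluded) and `cell_gaps`
#'   (region x category cells with no candidates).
#' @export
select_orthogonal <- function(sites, n_target = 54, distance = "gower") {
  stopifnot(is.data.frame(sites),
            all(c("site_id", "region") %in% names(sites)))
  if (n_target > nrow(sites))
    stop("n_target (", n_target, ") exceeds population size (",
         nrow(sites), ")")
  sites$site_id <- as.character(sites$site_id)
  if (anyDuplicated(sites$site_id)) stop("duplicate site ids")
  if (!all(c("ti", "mi") %in% names(sites)))
    sites <- climate_categories(sites)
  if (!all(c("pco1", "pco2") %in% names(sites))) {
    pc <- pcoa_soil_landform(sites, distance = distance)
    sites$pco1 <- pc$pco1
    sites$pco2 <- pc$pco2
  }
  sites$.radius <- sqrt(sites$pco1^2 + sites$pco2^2)
  cats <- levels(interaction(sites$mi, sites$ti, sep = ":"))
  regions <- sort(unique(as.character(sites$region)))
  cat_of <- interaction(sites$mi, sites$ti, sep = ":")
  # equal apportionment over the 4 categories, capped by availability
  cat_counts <- as.integer(table(cat_of)[cats])
  cat_quota <- .apportion(cat_counts, rep(1, length(cats)), n_target)
  selected <- character(0)
  gaps <- character(0)
  for (ci in seq_along(cats)) {
    in_cat <- cat_of == cats[ci]
    cell_counts <- vapply(regions, function(r)
      sum(in_cat & sites$region == r), integer(1))
    if (any(cell_counts == 0L))
      gaps <- c(gaps, paste(regions[cell_counts == 0L], cats[ci], sep = " x "))
    reg_quota <- .apportion(cell_counts, rep(1, length(regions)),
                            cat_quota[ci])
    for (ri in seq_along(regions)) {
      idx <- which(in_cat & sites$region == regions[ri])
      selected <- c(selected,
                    .pick_spread(sites$site_id[idx], sites$.radius[idx],
                                 reg_quota[ri]))
    }
  }
  if (length(gaps))
    warning("some region x climate-category combinations have no ",
            "candidates and were not sampled: ",
            paste(gaps, collapse = "; "))
  if (length(selected) < n_target)
    warning("only ", length(selected), " of ", n_target,
            " sites could be selected from the available cells")
  selected <- .polish_orthogonality(sites, selected, cat_of)
  sites$selected <- sites$site_id %in% selected
  sites$.radius <- NULL
  structure(list(selected = sort(selected), sites = sites,
                 orthogonality_report =
                   design_orthogonality(sites[sites$selected, , drop = FALSE]),
                 cell_gaps = gaps),
            class = "design_selection")
}

# Deterministic local search on the design's maximum absolute term
# correlation, the explicit goal of the selection. Stage 1 swaps a selected
# site for an unselected candidate of the same region x climate cell
# (stratification intact); stage 2 also allows swaps across regions within
# the same climate category — structural gaps (a region lacking a climate
# class) can only be traded off that way — while every region keeps at
# least half of its initial representation.
.polish_orthogonality <- function(sites, selected, cat_of, max_swaps = 40L) {
  ids <- sites$site_id
  reg <- as.character(sites$region)
  cat_chr <- as.character(cat_of)
  m <- cbind(TI = as.numeric(sites$ti == levels(sites$ti)[2L]),
             MI = as.numeric(sites$mi == levels(sites$mi)[2L]),
             PCo1 = sites$pco1, PCo2 = sites$pco2)
  regs <- sort(unique(reg))
  if (length(regs) > 1L)
    for (r in regs) m <- cbind(m, as.numeric(reg == r))
  is_dummy <- c(rep(FALSE, 4L), rep(TRUE, max(length(regs) - 0L, 0L)))[
    seq_len(ncol(m))]
  score <- function(in_sel) {
    mm <- m[in_sel, , drop = FALSE]
    keep <- apply(mm, 2L, function(col) stats::sd(col) > 0)
    cors <- suppressWarnings(stats::cor(mm[, keep, drop = FALSE]))
    dd <- is_dummy[keep]
    cors[dd, dd] <- 0
    diag(cors) <- 0
    max(abs(cors), na.rm = TRUE)
  }
  in_sel <- ids %in% selected
  best <- score(in_sel)
  init_reg <- table(factor(reg[in_sel], levels = regs))
  floor_reg <- stats::setNames(pmax(1L, floor(as.numeric(init_reg) / 2)),
                               names(init_reg))
  find_swap <- function(stage) {
    sel_idx <- which(in_sel)
    for (i in sel_idx[order(ids[sel_idx])]) {
      mates <- if (stage == 1L) which(!in_sel & reg == reg[i] &
                                        cat_chr == cat_chr[i])
      else which(!in_sel & cat_chr == cat_chr[i])
      for (j in mates[order(ids[mates])]) {
        if (stage == 2L && reg[j] != reg[i] &&
            sum(in_sel & reg == reg[i]) - 1L < floor_reg[[reg[i]]]) next
        trial <- in_sel
        trial[i] <- FALSE
        trial[j] <- TRUE
        sc <- score(trial)
        if (sc < best - 1e-9) return(list(trial = trial, sc = sc))
      }
    }
    NULL
  }
  for (stage in 1:2) {
    swaps <- 0L
    repeat {
      sw <- find_swap(stage)
      if (is.null(sw) || swaps >= max_swaps) break
      in_sel <- sw$trial
      best <- sw$sc
      swaps <- swaps + 1L
    }
  }
  ids[in_sel]
}

#' Maximum absolute correlation among design terms
#'
#' Quality metric of a gradient-study design: the largest absolute Pearson
#' correlation among the temperature category, moisture category, PCo1, PCo2
#' and region indicator variables. Pairs of two region dummies are excluded
#' (they are negatively correlated by construction).
#'
#' @param sites data frame with `ti`, `mi`, `pco1`, `pco2`, `region`.
#' @return the maximum absolute off-diagonal correlation.
#' @export
design_orthogonality <- function(sites) {
  stopifnot(all(c("ti", "mi", "pco1", "pco2", "region") %in% names(sites)))
  m <- cbind(TI = as.numeric(sites$ti == levels(sites$ti)[2L]),
             MI = as.numeric(sites$mi == levels(sites$mi)[2L]),
             PCo1 = sites$pco1, PCo2 = sites$pco2)
  reg <- factor(sites$region)
  dummies <- NULL
  if (nlevels(reg) > 1L) {
    dummies <- stats::model.matrix(~ reg - 1)
    colnames(dummies) <- paste0("BGR_", levels(reg))
  }
  full <- cbind(m, dummies)
  keep <- apply(full, 2L, function(col) stats::sd(col) > 0)
  full <- full[, keep, drop = FALSE]
  cors <- suppressWarnings(stats::cor(full))
  is_dummy <- grepl("^BGR_", colnames(full))
  cors[is_dummy, is_dummy] <- 0     # dummy-vs-dummy pairs are structural
  diag(cors) <- 0
  max(abs(cors), na.rm = TRUE)
}
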