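#' Standardize site-level covariates
#'
#' Mean-centers and scales each covariate column using the population-SD
#' convention (`sqrt(mean((x - mean(x))^2))`). The returned scaling constants
#' allow an exact back-transform, and transform of new (e.g. frame-wide)
#' covariate tables onto the fitted scale.
#'
#' @param raw_table data frame or matrix of per-site covariates (one row per
#'   site).
#' @param scaling optional scaling table from a previous call; when supplied,
#'   its constants are applied instead of recomputing them.
#' @return list with `standardized` (same shape as input), and `scaling`
#'   (data frame with columns `covariate`, `mean`, `sd`).
#' @examples
#' standardize_covariates(data.frame(forest = c(2, 4, 6)))$standardized
#' @export
standardize_covariates <- function(raw_table, scaling = NULL) {
  raw <- as.data.frame(raw_table)
  if (ncol(raw) == 0) {
    return(list(standardized = raw,
                scaling = data.frame(covariate = character(), mean = numeric(),
                                     sd = numeric())))
  }
  if (is.null(scaling)) {
    mu <- vapply(raw, mean, numeric(1))
    sdev <- vapply(raw, function(x) sqrt(mean((x - mean(x))^2)), numeric(1))
    bad <- names(raw)[sdev == 0]
    if (length(bad)) {
      stop("zero variance in covariate(s): ", paste(bad, collapse = ", "))
    }
    scaling <- data.frame(covariate = names(raw), mean = unname(mu),
                          sd = unname(sdev), stringsAsFactors = FALSE)
  } else {
    miss <- setdiff(names(raw), scaling$covariate)
    if (length(miss)) stop("no scaling constants for: ", paste(miss, collapse = ", "))
  }
  out <- raw
  for (nm in names(raw)) {
    row <- scaling[scaling$covariate == nm, ]
    out[[nm]] <- (raw[[nm]] - row$mean) / row$sd
  }
  list(standardized = out, scaling = scaling)
}

#' Invert a covariate standardization
#'
#' @param std_table standardized covariate table.
#' @param scaling scaling table from [standardize_covariates()].
#' @return data frame on the original scale.
#' @export
unstandardize_covariates <- function(std_table, scaling) {
  std <- as.data.frame(std_table)
  out <- std
  for (nm in names(std)) {
    row <- scaling[scaling$covariate == nm, ]
    if (nrow(row) != 1) stop("no scaling constants for: ", nm)
    out[[nm]] <- std[[nm]] * row$sd + row$mean
  }
  out
}

#' Detection/nondetection survey dataset
#'
#' Bundles the binary detection histories `y[i, t, j]` (site, season, visit),
#' visit dates, standardized site covariates, and site coordinates into the
#' container the model-fitting functions consume. Covariates and day-of-year
#' visit dates are standardized internally (population-SD convention) and the
#' constants stored, so frame-wide prediction uses identical scaling.
#'
#' @param y binary array `n x T x J`; `NA` marks missing visits.
#' @param date numeric array of day-of-year visit dates matching `y`; entries
#'   for missing visits may be `NA`.
#' @param covariates per-site covariate data frame (raw scale unless `scaling`
#'   is supplied).
#' @param coords two-column matrix/data frame of site coordinates in km.
#' @param site_id optional site identifiers (default `1:n`).
#' @param years optional integer vector of calendar years (length `T`).
#' @param scaling optional pre-computed covariate scaling (as returned in
#'   `$scaling`); when given, `covariates` are assumed already standardized
#'   with those constants.
#' @param date_scaling optional `c(mean, sd)` for dates.
#' @return object of class `survey_dataset`.
#' @export
survey_dataset <- function(y, date = NULL, covariates = NULL, coords = NULL,
                           site_id = NULL, years = NULL, scaling = NULL,
                           date_scaling = NULL) {
  y <- as.array(y)
  if (length(dim(y)) != 3) stop("y must be an n x T x J array")
  n <- dim(y)[1]; T <- dim(y)[2]; J <- dim(y)[3]
  if (n < 1 || T < 1 || J < 1) stop("need n >= 1, T >= 1, J >= 1")
  vals <- y[!is.na(y)]
  if (length(vals) && !all(vals %in% c(0, 1))) stop("y entries must be 0, 1 or NA")
  obs_per_site <- apply(!is.na(y), 1, sum)
  if (any(obs_per_site == 0)) {
    stop("site(s) without any non-missing visit: ",
         paste(which(obs_per_site == 0), collapse = ", "))
  }

  if (is.null(date)) date <- array(NA_real_, dim(y))
  date <- as.array(date)
  if (!all(dim(date) == dim(y))) stop("date dimensions must match y")
  if (any(!is.na(y) & is.na(date))) stop("observed visits must carry a date")

  if (is.null(covariates)) covariates <- data.frame(row.names = seq_len(n))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) stop("covariates must have one row per site")
  std <- standardize_covariates(covariates, scaling = scaling)

  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 2) stop("coords must be n x 2")
    colnames(coords) <- c("x_km", "y_km")
  }

  obs_dates <- date[!is.na(y)]
  if (is.null(date_scaling)) {
    if (length(obs_dates)) {
      dmu <- mean(obs_dates)
      dsd <- sqrt(mean((obs_dates - dmu)^2))
      if (dsd == 0) dsd <- 1  # single shared date: centered, unscaled
    } else {
      dmu <- 0; dsd <- 1
    }
    date_scaling <- c(mean = dmu, sd = dsd)
  }
  date_std <- (date - date_scaling[["mean"]]) / date_scaling[["sd"]]
  date_std[is.na(date_std)] <- 0  # unused by the likelihood; keeps arrays dense

  structure(list(
    y = y,
    date = date_std,
    date_raw = date,
    covariates = as.matrix(std$standardized),
    scaling = std$scaling,
    date_scaling = date_scaling,
    coords = coords,
    site_id = site_id %||% seq_len(n),
    years = years %||% seq_len(T)
  ), class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  d <- dim(x$y)
  cat("survey_dataset:", d[1], "sites x", d[2], "seasons x", d[3], "visits\n")
  cat("  detections:", sum(x$y == 1, na.rm = TRUE), " missing visits:",
      sum(is.na(x$y)), "\n")
  if (ncol(x$covariates)) {
    cat("  covariates:", paste(colnames(x$covariates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.survey_dataset <- function(x) dim(x$y)

#' Read a survey dataset from the standard CSV pair
#'
#' `detections.csv` holds one row per visit with columns `site_id`, `year`,
#' `visit`, `detected` (0/1/empty for missing) and `date` (ISO `yyyy-mm-dd`);
#' `sites.csv` holds `site_id`, `x_km`, `y_km` and the covariate columns
#' `forest_pct`, `elev_m`, `precip_mm`, `rough_sd_m`.
#'
#' @param detections_csv,sites_csv file paths.
#' @return a [survey_dataset()].
#' @export
read_survey_data <- function(detections_csv, sites_csv) {
  det <- utils::read.csv(detections_csv, stringsAsFactors = FALSE)
  sites <- utils::read.csv(sites_csv, stringsAsFactors = FALSE)
  need <- c("site_id", "year", "visit", "detected", "date")
  if (!all(need %in% names(det))) {
    stop("detections.csv must have columns: ", paste(need, collapse = ", "))
  }
  site_id <- sites$site_id
  years <- sort(unique(det$year))
  n <- length(site_id); T <- length(years); J <- max(det$visit)
  y <- array(NA_real_, c(n, T, J))
  date <- array(NA_real_, c(n, T, J))
  i <- match(det$site_id, site_id)
  if (anyNA(i)) stop("detections.csv references site_id missing from sites.csv")
  t <- match(det$year, years)
  idx <- cbind(i, t, det$visit)
  y[idx] <- ifelse(is.na(det$detected) | det$detected == "", NA_real_,
                   as.numeric(det$detected))
  doy <- as.POSIXlt(as.Date(det$date))$yday + 1
  date[idx] <- doy
  covs <- sites[, intersect(c("forest_pct", "elev_m", "precip_mm", "rough_sd_m"),
                            names(sites)), drop = FALSE]
  names(covs) <- c(forest_pct = "forest", elev_m = "elevation",
                   precip_mm = "precipitation", rough_sd_m = "roughness")[names(covs)]
  survey_dataset(y, date, covs, coords = sites[, c("x_km", "y_km")],
                 site_id = site_id, years = years)
}

#' Write a survey dataset as the standard CSV pair
#'
#' @param data a [survey_dataset()] whose covariates carry raw-scale
#'   constants (i.e. built from raw covariates).
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_survey_data <- function(data, dir) {
  stopifnot(inherits(data, "survey_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(data$y)
  idx <- which(!is.na(data$date_raw) | !is.na(data$y), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
  yr <- data$years[idx[, 2]]
  doy <- data$date_raw[idx]
  iso <- as.Date(doy - 1, origin = paste0(yr, "-01-01"))
  det <- data.frame(
    site_id = data$site_id[idx[, 1]],
    year = yr,
    visit = idx[, 3],
    detected = data$y[idx],
    date = format(iso, "%Y-%m-%d")
  )
  raw <- unstandardize_covariates(data$covariates, data$scaling)
  names(raw) <- c(forest = "forest_pct", elevation = "elev_m",
                  precipitation = "precip_mm", roughness = "rough_sd_m")[names(raw)]
  sites <- data.frame(site_id = data$site_id,
                      x_km = data$coords[, 1], y_km = data$coords[, 2], raw)
  fd <- file.path(dir, "detections.csv")
  fs <- file.path(dir, "sites.csv")
  utils::write.csv(det, fd, row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(sites, fs, row.names = FALSE, quote = FALSE, na = "")
  invisible(c(detections = fd, sites = fs))
}
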