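#' Model parameter names
#'
#' Canonical parameter naming used by priors, the sampler and all summaries:
#' `beta0`, `beta_<covariate>`, `a_1 ... a_{T-1}`, `b_1 ... b_{T-1}` (or
#' single `a`, `b` when transitions are shared), `beta_zint` when the
#' interaction term is enabled, and the detection-level `alpha0`, `alpha1`.
#'
#' @param covariate_names character vector of covariate names.
#' @param n_transitions number of transitions (`T - 1`).
#' @param share_transitions single `a`, `b` shared across transitions?
#' @param interaction include the covariate-by-previous-state term?
#' @return list with `occupancy` and `detection` name vectors.
#' @export
model_param_names <- function(covariate_names = character(), n_transitions = 0,
                              share_transitions = FALSE, interaction = FALSE) {
  occ <- c("beta0",
           if (length(covariate_names)) paste0("beta_", covariate_names))
  if (n_transitions > 0) {
    if (share_transitions) {
      occ <- c(occ, "a", "b")
    } else {
      occ <- c(occ, paste0("a_", seq_len(n_transitions)),
               paste0("b_", seq_len(n_transitions)))
    }
  }
  if (interaction) occ <- c(occ, "beta_zint")
  list(occupancy = occ, detection = c("alpha0", "alpha1"))
}

new_prior_spec <- function(entries, provenance) {
  stopifnot(all(c("parameter", "mean", "sd") %in% names(entries)))
  if (any(entries$sd <= 0)) {
    stop("nonpositive prior sd for: ",
         paste(entries$parameter[entries$sd <= 0], collapse = ", "))
  }
  if (anyDuplicated(entries$parameter)) stop("duplicate prior entries")
  structure(list(entries = entries[, c("parameter", "mean", "sd")],
                 provenance = provenance),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("prior_spec (", x$provenance, "), ", nrow(x$entries), " Normal entries\n",
      sep = "")
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Vague Normal priors
#'
#' Independent Normal(0, scale) priors for every named parameter. The
#' conventional "Normal(0,10)" of BUGS-family software states a precision of
#' 0.1, i.e. variance 10 (sd ~ 3.16): that reading keeps the prior
#' regularizing on the logit scale and is the default here. The meaning of
#' `scale` is switchable.
#'
#' @param param_names character vector of parameter names.
#' @param scale prior scale value (default 10).
#' @param convention how `scale` is read: `"variance"` (default), `"sd"`, or
#'   `"precision"`.
#' @return a `prior_spec` with provenance `"vague"`.
#' @export
vague_priors <- function(param_names, scale = 10,
                         convention = c("variance", "sd", "precision")) {
  if (!length(param_names)) stop("empty parameter name list")
  convention <- match.arg(convention)
  sd <- switch(convention,
               variance = sqrt(scale),
               sd = scale,
               precision = sqrt(1 / scale))
  new_prior_spec(data.frame(parameter = param_names, mean = 0, sd = sd,
                            stringsAsFactors = FALSE),
                 provenance = "vague")
}

#' Empirically informed priors from a previous period's posterior summary
#'
#' Builds the prior specification for a new monitoring period from the
#' posterior means and SDs of a previous period's occupancy-level parameters
#' `[beta, a_t, b_t]`. Detection-level parameters always receive vague
#' priors: detection conditions (equipment, call processing) change between
#' periods, so that sub-model is refit from scratch. A summary row named
#' `"a"` (or `"b"`) is applied to every transition of the new model.
#'
#' @param period1_summary data frame with columns `parameter`, `mean`, `sd`
#'   covering all occupancy-level parameters (generic `a`, `b` allowed).
#' @param param_names parameter naming from [model_param_names()] (list with
#'   `occupancy` and `detection` components).
#' @param detection_scale,detection_convention vague-prior scale for the
#'   detection-level parameters (see [vague_priors()]).
#' @param provenance free-text provenance tag.
#' @return a `prior_spec`.
#' @export
informative_priors <- function(period1_summary, param_names,
                               detection_scale = 10,
                               detection_convention = "variance",
                               provenance = "period1-posterior") {
  s <- as.data.frame(period1_summary)
  if (!all(c("parameter", "mean", "sd") %in% names(s))) {
    stop("summary must have columns parameter, mean, sd")
  }
  lookup <- function(nm) {
    hit <- s[s$parameter == nm, ]
    if (nrow(hit) == 0 && grepl("^[ab]_[0-9]+$", nm)) {
      hit <- s[s$parameter == substr(nm, 1, 1), ]  # generic a/b row
    }
    if (nrow(hit) != 1) stop("missing occupancy-level prior for: ", nm)
    hit
  }
  occ <- do.call(rbind, lapply(param_names$occupancy, function(nm) {
    hit <- lookup(nm)
    data.frame(parameter = nm, mean = hit$mean, sd = hit$sd,
               stringsAsFactors = FALSE)
  }))
  det <- if (length(param_names$detection)) {
    vague_priors(param_names$detection, scale = detection_scale,
                 convention = detection_convention)$entries
  }
  new_prior_spec(rbind(occ, det), provenance = provenance)
}

#' Summarize posterior draws into a prior for the next period
#'
#' The posterior-to-prior scaffolding step: each listed parameter gets an
#' independent Normal prior with the mean and SD of its pooled posterior
#' draws. The result feeds [informative_priors()] unchanged.
#'
#' @param draws a `posterior_draws` object (see [fit_model()]).
#' @param params parameter names to summarize (default: all occupancy-level
#'   parameters in `draws`).
#' @return data frame with columns `parameter`, `mean`, `sd`.
#' @export
posterior_to_prior <- function(draws, params = NULL) {
  stopifnot(inherits(draws, "posterior_draws"))
  m <- draws_matrix(draws)
  if (nrow(m) < 100) stop("fewer than 100 retained draws: moments unstable")
  params <- params %||% draws$param_names$occupancy
  missing <- setdiff(params, colnames(m))
  if (length(missing)) stop("unknown parameter(s): ", paste(missing, collapse = ", "))
  out <- data.frame(parameter = params,
                    mean = colMeans(m[, params, drop = FALSE]),
                    sd = apply(m[, params, drop = FALSE], 2, stats::sd),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (any(out$sd == 0)) {
    stop("degenerate posterior (zero sd) for: ",
         paste(out$parameter[out$sd == 0], collapse = ", "))
  }
  out
}

#' Packaged previous-period posterior summaries
#'
#' Ships the occupancy-level posterior means and SDs from the 2010 close of
#' the first monitoring period for the two focal species, for use as
#' empirically informed priors on a new period's model.
#'
#' @param species `"hoary"` or `"little_brown"`.
#' @return data frame with columns `parameter`, `mean`, `sd`.
#' @export
period1_posterior_summary <- function(species = c("hoary", "little_brown")) {
  species <- match.arg(species)
  path <- system.file("extdata", paste0("priors_", species, ".json"),
                      package = "occutrend")
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  data.frame(parameter = names(spec$entries),
             mean = vapply(spec$entries, function(e) e$mean, numeric(1)),
             sd = vapply(spec$entries, function(e) e$sd, numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read / write a prior specification as JSON
#'
#' Format: `{"provenance": ..., "entries": {"<param>":
#' {"family": "normal", "mean": m, "sd": s}, ...}}`.
#'
#' @param path file path.
#' @return [read_priors()] returns a `prior_spec`; [write_priors()] its path,
#'   invisibly.
#' @export
read_priors <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- data.frame(
    parameter = names(spec$entries),
    mean = vapply(spec$entries, function(e) e$mean, numeric(1)),
    sd = vapply(spec$entries, function(e) e$sd, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  new_prior_spec(entries, provenance = spec$provenance %||% path)
}

#' @rdname read_priors
#' @param priors a `prior_spec`.
#' @export
write_priors <- function(priors, path) {
  stopifnot(inherits(priors, "prior_spec"))
  entries <- lapply(seq_len(nrow(priors$entries)), function(i) {
    list(family = "normal", mean = priors$entries$mean[i],
         sd = priors$entries$sd[i])
  })
  names(entries) <- priors$entries$parameter
  jsonlite::write_json(list(provenance = priors$provenance, entries = entries),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
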