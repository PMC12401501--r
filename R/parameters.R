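## Parameter container, validation, serialization, sampling and overrides.
##
## A `twin_params` object is a list with two components:
##   values  - nested list of all model inputs (see base_case_parameters())
##   priors  - data.frame describing the uncertainty distribution and clinical
##             range of every non-derived parameter, one row per scalar, in the
##             fixed order consumed by sample_parameters()
## Parameters are addressed by dot-paths into `values`, e.g.
## "screening.p_s1_le25", "rr_cerclage.ga_le28", "costs.nicu_per_admission.ga_le28",
## "baseline_birth_timing.cl_le15.ga_le28", "lifetable.a0", "utility.a50.ga_gt37".

DIST_FAMILIES <- c("beta", "lognormal", "gamma", "dirichlet", "fixed")

`%||%` <- function(a, b) if (is.null(a)) b else a

age_names <- function(ages) paste0("a", ages)

## ---- dot-path access --------------------------------------------------------

split_path <- function(name) strsplit(name, ".", fixed = TRUE)[[1]]

get_path <- function(x, parts, name) {
  if (length(parts) == 0L) {
    if (!is.numeric(x) || length(x) != 1L)
      stop("parameter path does not resolve to a scalar: ", name, call. = FALSE)
    return(as.numeric(x))
  }
  p <- parts[[1L]]
  if (is.matrix(x)) {
    if (length(parts) != 2L || !(p %in% rownames(x)) ||
        !(parts[[2L]] %in% colnames(x)))
      stop("unknown parameter: ", name, call. = FALSE)
    return(x[p, parts[[2L]]])
  }
  if (is.list(x)) {
    if (!(p %in% names(x))) stop("unknown parameter: ", name, call. = FALSE)
    return(get_path(x[[p]], parts[-1L], name))
  }
  if (!is.null(names(x)) && p %in% names(x) && length(parts) == 1L)
    return(as.numeric(x[[p]]))
  stop("unknown parameter: ", name, call. = FALSE)
}

set_path <- function(x, parts, value, name) {
  if (length(parts) == 0L) return(value)
  p <- parts[[1L]]
  if (is.matrix(x)) {
    if (length(parts) != 2L || !(p %in% rownames(x)) ||
        !(parts[[2L]] %in% colnames(x)))
      stop("unknown parameter: ", name, call. = FALSE)
    x[p, parts[[2L]]] <- value
    return(x)
  }
  if (is.list(x)) {
    if (!(p %in% names(x))) stop("unknown parameter: ", name, call. = FALSE)
    x[[p]] <- set_path(x[[p]], parts[-1L], value, name)
    return(x)
  }
  if (!is.null(names(x)) && p %in% names(x) && length(parts) == 1L) {
    x[[p]] <- value
    return(x)
  }
  stop("unknown parameter: ", name, call. = FALSE)
}

#' Read a single parameter value by name
#'
#' @param params a \code{twin_params} object.
#' @param name dot-path of the parameter, e.g. \code{"screening.p_s1_le25"} or
#'   \code{"costs.nicu_per_admission.ga_34_37"}.
#' @return the numeric value.
#' @export
param_value <- function(params, name) {
  stopifnot(inherits(params, "twin_params"))
  get_path(params$values, split_path(name), name)
}

## Mathematical support ("hard range") of a parameter, by path. Clinical
## ranges (priors$low/high) are narrower and drive DSA grid defaults; hard
## ranges drive validation and may be exceeded by neither DSA nor overrides.
hard_range <- function(name) {
  top <- split_path(name)[[1L]]
  switch(top,
    screening = ,
    stillbirth_prob = ,
    nicu_admission = ,
    cesarean_rate = ,
    treatment_uptake = ,
    nsi_proportion = ,
    lifetable = ,
    baseline_birth_timing = c(0, 1),
    rr_progesterone = ,
    rr_cerclage = ,
    hazard_ratio = c(1e-12, Inf),
    costs = ,
    annual_cost = ,
    annual_cost_after9 = ,
    n_scans = c(0, Inf),
    utility = ,
    u_nsi = ,
    u_no_nsi = c(UTILITY_MIN, 1),
    discount_rate = c(0, 0.999),
    twin_multiplier = c(1, 2),
    c(-Inf, Inf))
}

## ---- validation -------------------------------------------------------------

chk <- function(ok, name, why) {
  if (!all(ok)) stop("invalid parameter '", name, "': ", why, call. = FALSE)
}

validate_values <- function(v) {
  req <- c("screening", "rr_progesterone", "rr_cerclage",
           "baseline_birth_timing", "stillbirth_prob", "nicu_admission",
           "costs", "cesarean_rate", "n_scans", "annual_cost",
           "annual_cost_after9", "lifetable", "hazard_ratio",
           "nsi_proportion", "u_nsi", "u_no_nsi", "utility",
           "discount_rate", "treatment_uptake", "twin_multiplier", "options")
  miss <- setdiff(req, names(v))
  if (length(miss)) stop("missing parameter section(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)

  sc <- v$screening
  sc_req <- c("p_s1_le25", "p_s1_le15_given_le25", "p_s2_le25_given_s1_neg",
              "p_s2_le15_given_le25_s1neg")
  miss <- setdiff(sc_req, names(sc))
  if (length(miss)) stop("missing parameter(s): ",
                         paste0("screening.", miss, collapse = ", "),
                         call. = FALSE)
  for (nm in sc_req)
    chk(sc[[nm]] >= 0 && sc[[nm]] <= 1, paste0("screening.", nm),
        "probability must lie in [0, 1]")

  for (fld in c("rr_progesterone", "rr_cerclage")) {
    rr <- v[[fld]]
    chk(identical(names(rr), PRETERM_LEVELS), fld,
        "must be named by the four preterm GA categories")
    chk(all(rr > 0), fld, "relative risks must be > 0")
  }

  bt <- v$baseline_birth_timing
  chk(is.matrix(bt) && identical(rownames(bt), CL_LEVELS) &&
        identical(colnames(bt), GA_LEVELS), "baseline_birth_timing",
      "must be a 3 CL-stratum x 5 GA-category matrix")
  chk(all(bt >= 0), "baseline_birth_timing", "probabilities must be >= 0")
  bad <- abs(rowSums(bt) - 1) > 1e-9
  if (any(bad))
    stop("invalid parameter 'baseline_birth_timing.", CL_LEVELS[bad][1L],
         "': birth-timing probabilities must sum to 1 (found ",
         format(rowSums(bt)[bad][1L], digits = 12), ")", call. = FALSE)

  for (fld in c("stillbirth_prob", "nicu_admission")) {
    x <- v[[fld]]
    chk(identical(names(x), GA_LEVELS), fld, "must be named by GA category")
    chk(all(x >= 0 & x <= 1), fld, "probabilities must lie in [0, 1]")
  }

  co <- v$costs
  co_req <- c("ultrasound_per_scan", "progesterone_per_week",
              "cerclage_procedure", "vaginal_birth", "cesarean_birth",
              "nicu_per_admission")
  miss <- setdiff(co_req, names(co))
  if (length(miss)) stop("missing parameter(s): ",
                         paste0("costs.", miss, collapse = ", "), call. = FALSE)
  for (nm in setdiff(co_req, "nicu_per_admission"))
    chk(co[[nm]] >= 0, paste0("costs.", nm), "costs must be >= 0")
  chk(identical(names(co$nicu_per_admission), GA_LEVELS) &&
        all(co$nicu_per_admission >= 0), "costs.nicu_per_admission",
      "must be a nonnegative cost per GA category")

  chk(v$cesarean_rate >= 0 && v$cesarean_rate <= 1, "cesarean_rate",
      "probability must lie in [0, 1]")
  chk(identical(names(v$n_scans), STRATEGIES) && all(v$n_scans >= 0),
      "n_scans", "must be a nonnegative scan count per strategy")

  ac <- v$annual_cost
  chk(is.matrix(ac) && identical(rownames(ac), age_names(0:9)) &&
        identical(colnames(ac), GA_LEVELS) && all(ac >= 0), "annual_cost",
      "must be a nonnegative ages-0-9 x GA-category cost matrix")
  chk(v$annual_cost_after9 >= 0, "annual_cost_after9", "costs must be >= 0")

  lt <- v$lifetable
  chk(identical(names(lt), age_names(0:99)) && all(lt >= 0 & lt <= 1),
      "lifetable", "must give an annual death probability in [0, 1] for ages 0-99")

  hr <- v$hazard_ratio
  chk(is.matrix(hr) && identical(rownames(hr), age_names(0:45)) &&
        identical(colnames(hr), GA_LEVELS), "hazard_ratio",
      "must be an ages-0-45 x GA-category matrix")
  chk(all(hr > 0), "hazard_ratio", "hazard ratios must be > 0")

  chk(identical(names(v$nsi_proportion), GA_LEVELS) &&
        all(v$nsi_proportion >= 0 & v$nsi_proportion <= 1),
      "nsi_proportion", "probabilities must lie in [0, 1]")
  for (fld in c("u_nsi", "u_no_nsi")) {
    u <- v[[fld]]
    chk(identical(names(u), age_names(AGES)) &&
          all(u >= UTILITY_MIN & u <= 1), fld,
        "utilities must lie in the HUI3 range [-0.36, 1] for ages 0-100")
  }
  ut <- v$utility
  chk(is.matrix(ut) && identical(rownames(ut), age_names(AGES)) &&
        identical(colnames(ut), GA_LEVELS) &&
        all(ut >= UTILITY_MIN & ut <= 1), "utility",
      "must be an ages-0-100 x GA-category matrix in the HUI3 range")

  chk(v$discount_rate >= 0 && v$discount_rate < 1, "discount_rate",
      "must lie in [0, 1)")
  chk(v$treatment_uptake >= 0 && v$treatment_uptake <= 1, "treatment_uptake",
      "probability must lie in [0, 1]")
  chk(v$twin_multiplier >= 1 && v$twin_multiplier <= 2, "twin_multiplier",
      "must lie in [1, 2]")

  op <- v$options
  chk(identical(names(op$ga_midpoint), GA_LEVELS) &&
        !is.unsorted(op$ga_midpoint), "options.ga_midpoint",
      "must be increasing gestational weeks per GA category")
  chk(all(c("s1", "s2") %in% names(op$prog_start_week)), "options.prog_start_week",
      "must give start weeks for screens 1 and 2")
  invisible(v)
}

validate_priors <- function(priors, values) {
  need <- c("name", "family", "a", "b", "group", "low", "high")
  miss <- setdiff(need, names(priors))
  if (length(miss)) stop("priors table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(priors))) {
    nm <- priors$name[i]
    fam <- priors$family[i]
    a <- priors$a[i]; b <- priors$b[i]
    if (!(fam %in% DIST_FAMILIES))
      stop("invalid parameter '", nm, "': unknown distribution family '",
           fam, "'", call. = FALSE)
    ok <- switch(fam,
      beta = a > 0 && b > 0,
      lognormal = is.finite(a) && b > 0,
      gamma = a > 0 && b > 0,
      dirichlet = a > 0,
      fixed = TRUE)
    if (!isTRUE(ok))
      stop("invalid parameter '", nm, "': ", fam,
           " distribution parameters out of range (a = ", a, ", b = ", b, ")",
           call. = FALSE)
    get_path(values, split_path(nm), nm)  # must resolve
    if (is.finite(priors$low[i]) && is.finite(priors$high[i]) &&
        priors$low[i] > priors$high[i])
      stop("invalid parameter '", nm, "': clinical range low > high",
           call. = FALSE)
  }
  invisible(priors)
}

#' Construct a validated model parameter set
#'
#' Most users obtain parameter sets from \code{\link{base_case_parameters}},
#' \code{\link{generate_parameter_set}} or \code{\link{load_parameters}};
#' this constructor validates an assembled values/priors pair.
#'
#' @param values nested list of model inputs (see
#'   \code{\link{base_case_parameters}} for the layout).
#' @param priors data.frame with columns \code{name} (dot-path),
#'   \code{family} (one of beta, lognormal, gamma, dirichlet, fixed),
#'   \code{a}, \code{b} (distribution parameters), \code{group} (joint-draw
#'   group for dirichlet rows, \code{NA} otherwise) and \code{low},
#'   \code{high} (clinical range used as the default DSA grid).
#' @return an object of class \code{twin_params}.
#' @export
VALUE_ORDER <- c("screening", "rr_progesterone", "rr_cerclage",
                 "baseline_birth_timing", "stillbirth_prob", "nicu_admission",
                 "costs", "cesarean_rate", "n_scans", "annual_cost",
                 "annual_cost_after9", "lifetable", "hazard_ratio",
                 "nsi_proportion", "u_nsi", "u_no_nsi", "utility",
                 "discount_rate", "treatment_uptake", "twin_multiplier",
                 "options")

twin_params <- function(values, priors) {
  values <- values[c(intersect(VALUE_ORDER, names(values)),
                     setdiff(names(values), VALUE_ORDER))]
  validate_values(values)
  priors <- as.data.frame(priors, stringsAsFactors = FALSE)
  validate_priors(priors, values)
  structure(list(values = values, priors = priors), class = "twin_params")
}

#' @export
print.twin_params <- function(x, ...) {
  v <- x$values
  n_sampled <- sum(x$priors$family != "fixed")
  cat("Twin-pregnancy CL-screening model parameters (2023 CAD)\n")
  cat(sprintf("  screen-1 P(CL<=25mm): %.3f; screen-2 P(CL<=25mm | s1 neg): %.3f\n",
              v$screening$p_s1_le25, v$screening$p_s2_le25_given_s1_neg))
  cat(sprintf("  discount rate: %.1f%%/yr; treatment uptake: %.0f%%; twin multiplier: %g\n",
              100 * v$discount_rate, 100 * v$treatment_uptake,
              v$twin_multiplier))
  cat(sprintf("  %d scalar parameters (%d with uncertainty distributions)\n",
              nrow(x$priors), n_sampled))
  invisible(x)
}

## ---- override ---------------------------------------------------------------

#' Override one model parameter
#'
#' Returns a copy of \code{params} with exactly one value changed; the input
#' is untouched. Values must respect the parameter's mathematical support but
#' may exceed its clinical range (deterministic sensitivity analysis does so
#' by design). Overriding a preterm birth-timing probability is permitted:
#' the term category always absorbs the residual mass when distributions are
#' adjusted downstream (see \code{\link{adjusted_birth_timing}}).
#'
#' @inheritParams param_value
#' @param value new numeric value.
#' @return a new \code{twin_params} object.
#' @export
override_parameter <- function(params, name, value) {
  stopifnot(inherits(params, "twin_params"))
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("override value for '", name, "' must be a finite numeric scalar",
         call. = FALSE)
  get_path(params$values, split_path(name), name)  # existence check
  rng <- hard_range(name)
  if (value < rng[1L] || value > rng[2L])
    stop("override value ", value, " for '", name,
         "' is outside its mathematical support [", rng[1L], ", ", rng[2L], "]",
         call. = FALSE)
  params$values <- set_path(params$values, split_path(name), value, name)
  params
}

## ---- sampling ---------------------------------------------------------------

#' Draw one joint parameter sample for probabilistic sensitivity analysis
#'
#' Every parameter with a non-fixed distribution in \code{params$priors} is
#' drawn independently: beta(a, b) for event/non-event probabilities,
#' lognormal(a, b) for relative risks (a = log-mean, b = SE on the log scale),
#' gamma(shape a, rate b) for unit costs, and a joint dirichlet draw (gamma
#' normalisation, concentration \code{a}) for each birth-timing simplex row.
#' Draws consume the RNG in the row order of the priors table, so a seed
#' identifies the same draw across machines. Fixed-family parameters are
#' returned unchanged.
#'
#' @inheritParams param_value
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return a new \code{twin_params} object with sampled values (priors
#'   unchanged, so the result can be resampled or inspected).
#' @export
sample_parameters <- function(params, seed) {
  stopifnot(inherits(params, "twin_params"))
  if (!missing(seed) && !is.null(seed)) set.seed(as.integer(seed))
  v <- params$values
  pr <- params$priors
  done_groups <- character(0)
  for (i in seq_len(nrow(pr))) {
    fam <- pr$family[i]
    if (fam == "fixed") next
    nm <- pr$name[i]
    if (fam == "dirichlet") {
      g <- pr$group[i]
      if (g %in% done_groups) next
      rows <- which(pr$group == g & pr$family == "dirichlet")
      draw <- stats::rgamma(length(rows), shape = pr$a[rows], rate = 1)
      draw <- draw / sum(draw)
      for (k in seq_along(rows))
        v <- set_path(v, split_path(pr$name[rows[k]]), draw[k], pr$name[rows[k]])
      done_groups <- c(done_groups, g)
    } else {
      x <- switch(fam,
        beta = stats::rbeta(1L, pr$a[i], pr$b[i]),
        lognormal = stats::rlnorm(1L, meanlog = pr$a[i], sdlog = pr$b[i]),
        gamma = stats::rgamma(1L, shape = pr$a[i], rate = pr$b[i]))
      v <- set_path(v, split_path(nm), x, nm)
    }
  }
  params$values <- v
  params
}

## ---- serialization ----------------------------------------------------------

## Fields stored as CSV sidecar files (large tables); everything else is
## inline YAML. Sidecar schemas: lifetable.csv has columns age,probability;
## the others have age,category,value with category in GA_LEVELS.
SIDE_FIELDS <- c("lifetable", "hazard_ratio", "utility", "annual_cost")

mat_to_long <- function(m) {
  ages <- as.integer(sub("^a", "", rownames(m)))
  data.frame(age = rep(ages, times = ncol(m)),
             category = rep(colnames(m), each = nrow(m)),
             value = as.vector(m))
}

long_to_mat <- function(df, ages, field) {
  need <- c("age", "category", "value")
  if (!all(need %in% names(df)))
    stop("sidecar for '", field, "' must have columns age,category,value",
         call. = FALSE)
  m <- matrix(NA_real_, nrow = length(ages), ncol = length(GA_LEVELS),
              dimnames = list(age_names(ages), GA_LEVELS))
  idx <- cbind(match(df$age, ages), match(df$category, GA_LEVELS))
  if (any(is.na(idx)))
    stop("sidecar for '", field, "' contains unknown ages or categories",
         call. = FALSE)
  m[idx] <- df$value
  if (any(is.na(m)))
    stop("sidecar for '", field, "' is missing ages/categories", call. = FALSE)
  m
}

#' Write a parameter set to a YAML master file with CSV sidecars
#'
#' The YAML file holds all scalar parameters and the priors table inline; the
#' four large tables (lifetable, hazard ratios, utilities, annual costs) are
#' written as plain CSV sidecar files next to it and referenced by name. All
#' monetary fields are 2023 Canadian dollars.
#'
#' @inheritParams param_value
#' @param path destination YAML file; sidecars are written to its directory.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{load_parameters}}
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "twin_params"))
  v <- params$values
  dir <- dirname(path)
  stem <- sub("\\.ya?ml$", "", basename(path))
  sidecars <- list()
  for (fld in SIDE_FIELDS) {
    fn <- paste0(stem, "_", fld, ".csv")
    if (fld == "lifetable") {
      df <- data.frame(age = 0:99, probability = unname(v$lifetable))
    } else {
      df <- mat_to_long(v[[fld]])
    }
    utils::write.csv(df, file.path(dir, fn), row.names = FALSE, quote = FALSE)
    sidecars[[fld]] <- fn
  }
  to_yamlable <- function(x) {
    if (is.list(x)) lapply(x, to_yamlable)
    else if (!is.null(names(x)) && length(x) > 1L) as.list(x)
    else unname(x)
  }
  inline <- v[setdiff(names(v), SIDE_FIELDS)]
  inline$baseline_birth_timing <-
    lapply(stats::setNames(CL_LEVELS, CL_LEVELS),
           function(s) as.list(v$baseline_birth_timing[s, ]))
  doc <- list(
    meta = list(model = "twincua parameter set", currency = "2023 CAD",
                schema = 1L),
    sidecars = sidecars,
    values = to_yamlable(inline),
    priors = lapply(seq_len(nrow(params$priors)), function(i)
      as.list(params$priors[i, ])))
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Load and validate a parameter set from a YAML file
#'
#' Reads the schema written by \code{\link{write_parameters}}: a YAML master
#' document plus CSV sidecars for the lifetable (\code{age,probability}) and
#' the hazard-ratio, utility and annual-cost tables
#' (\code{age,category,value}). Every invariant is checked and violations are
#' reported with the offending parameter's name.
#'
#' @param path path to the YAML master file.
#' @return a validated \code{twin_params} object.
#' @examples
#' p <- load_parameters(system.file("extdata", "synthetic_base_case.yaml",
#'                                  package = "twincua"))
#' param_value(p, "screening.p_s1_le25")
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  for (sec in c("values", "priors", "sidecars"))
    if (is.null(doc[[sec]]))
      stop("parameter file missing section: ", sec, call. = FALSE)
  v <- doc$values
  dir <- dirname(path)
  for (fld in SIDE_FIELDS) {
    fn <- doc$sidecars[[fld]]
    if (is.null(fn)) stop("missing sidecar reference: ", fld, call. = FALSE)
    fp <- file.path(dir, fn)
    if (!file.exists(fp)) stop("sidecar file not found: ", fp, call. = FALSE)
    df <- utils::read.csv(fp)
    if (fld == "lifetable") {
      if (!all(c("age", "probability") %in% names(df)))
        stop("sidecar for 'lifetable' must have columns age,probability",
             call. = FALSE)
      df <- df[order(df$age), ]
      if (!identical(as.integer(df$age), 0:99))
        stop("sidecar for 'lifetable' must cover ages 0-99", call. = FALSE)
      v$lifetable <- stats::setNames(df$probability, age_names(0:99))
    } else {
      ages <- if (fld == "annual_cost") 0:9 else if (fld == "hazard_ratio") 0:45 else AGES
      v[[fld]] <- long_to_mat(df, ages, fld)
    }
  }
  bt <- v$baseline_birth_timing
  if (is.null(bt)) stop("missing parameter section(s): baseline_birth_timing",
                        call. = FALSE)
  v$baseline_birth_timing <-
    do.call(rbind, lapply(stats::setNames(CL_LEVELS, CL_LEVELS), function(s) {
      row <- unlist(bt[[s]])
      if (is.null(bt[[s]]) || !identical(names(row), GA_LEVELS))
        stop("invalid parameter 'baseline_birth_timing.", s,
             "': must give all five GA categories", call. = FALSE)
      row
    }))
  for (fld in c("screening", "costs", "options"))
    if (!is.null(v[[fld]])) v[[fld]] <- lapply(v[[fld]], function(x)
      if (is.list(x)) unlist(x) else x)
  for (fld in c("rr_progesterone", "rr_cerclage", "stillbirth_prob",
                "nicu_admission", "n_scans", "nsi_proportion",
                "u_nsi", "u_no_nsi"))
    if (!is.null(v[[fld]])) v[[fld]] <- unlist(v[[fld]])
  priors <- do.call(rbind, lapply(doc$priors, function(r)
    data.frame(name = r$name, family = r$family,
               a = as.numeric(r$a %||% NA), b = as.numeric(r$b %||% NA),
               group = as.character(r$group %||% NA),
               low = as.numeric(r$low %||% NA),
               high = as.numeric(r$high %||% NA),
               stringsAsFactors = FALSE)))
  twin_params(v, priors)
}

#' Path to a bundled example parameter file
#'
#' @param file file name within the package's \code{extdata} directory;
#'   defaults to the synthetic base-case YAML master file.
#' @return full path to the file.
#' @export
twincua_example <- function(file = "synthetic_base_case.yaml") {
  system.file("extdata", file, package = "twincua", mustWork = TRUE)
}
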