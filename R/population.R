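#' Default thermosensitive fiber class mixture
#'
#' Proportions over the six thermosensitive fiber classes observed in
#' forepaw recordings, taken from the recorded tallies
#' (C-MH 20, C-MHC 6, C-MC 7, C-C 2 of 37 thermosensitive C-fibers, plus
#' one A-MH and one A-MC), renormalised over the named classes.
#'
#' @return A named numeric vector summing to 1.
#' @export
default_class_mix <- function() {
  c("C-MH" = 20, "C-MHC" = 6, "C-MC" = 7, "C-C" = 2,
    "A-MH" = 1, "A-MC" = 1) / 37
}

# Classes excited by skin cooling (used by genotype presets).
COOL_CLASSES <- c("C-MHC", "C-MC", "C-C", "A-MC")
# Classes excited by skin warming/heat.
HEAT_CLASSES <- c("C-MH", "C-MHC", "A-MH")

#' Specification of a simulated afferent population
#'
#' Describes the innervation of the stimulated skin patch: fiber density,
#' contact area, the fraction of fibers responsive to innocuous temperature
#' change, the class mixture of the thermosensitive subset, the fraction of
#' thermosensitive fibers with cool-driven ongoing activity, and a genotype
#' preset. Defaults are the measured forepaw values: up to 176 C-fibers per
#' mm2, ~36 percent thermosensitive, ~22 mm2 Peltier contact area, and 19
#' percent of thermosensitive fibers tonically active.
#'
#' @param density Fiber density, fibers/mm2.
#' @param thermo_fraction Fraction of fibers responsive to innocuous
#'   temperature change.
#' @param area Stimulated skin area, mm2.
#' @param class_mix Named proportions over thermosensitive fiber classes;
#'   must sum to 1.
#' @param ongoing_fraction Fraction of thermosensitive fibers with ongoing
#'   (tonic, cool-driven) activity.
#' @param genotype Preset name; see \code{\link{genotype_preset}}.
#' @param t_on_range Range from which warm-excited absolute thresholds are
#'   drawn uniformly, degC. Thresholds are absolute temperatures, so a
#'   22->32 degC step recruits few warm-excited fibers, and weakly.
#' @param gain_range Range of warm-excited gains, Hz/degC.
#' @param ongoing_range Range of tonic ongoing rates, Hz.
#' @param cool_gain Cooling gain of cool-driven fibers, Hz/degC.
#' @param warm_suppression_gain Fractional suppression per degC warming of
#'   tonic fibers (default 0.2: a 5 degC warm step silences).
#' @param r_max Warm-excited rate ceiling, Hz.
#' @param noxious_cutoff,noxious_scale Noxious-range gain rescaling applied
#'   to warm-excited fibers (genotype presets set these).
#' @param cool_gain_scale Multiplier on cooling gain (genotype presets).
#' @param seed Integer seed used when sampling fiber identities.
#' @return An object of class \code{population_spec}.
#' @export
population_spec <- function(density = 176, thermo_fraction = 0.36,
                            area = 22, class_mix = default_class_mix(),
                            ongoing_fraction = 0.19,
                            genotype = "wildtype",
                            t_on_range = c(33, 44), gain_range = c(1, 3),
                            ongoing_range = c(0.2, 6), cool_gain = 1,
                            warm_suppression_gain = 0.2, r_max = 30,
                            noxious_cutoff = Inf, noxious_scale = 1,
                            cool_gain_scale = 1, seed = NULL) {
  if (density <= 0 || area <= 0) stop("density and area must be > 0",
                                      call. = FALSE)
  if (thermo_fraction < 0 || thermo_fraction > 1 ||
      ongoing_fraction < 0 || ongoing_fraction > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (length(class_mix) == 0 || is.null(names(class_mix))) {
    stop("class_mix must be a non-empty named vector", call. = FALSE)
  }
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-8) {
    stop("class_mix must be non-negative and sum to 1", call. = FALSE)
  }
  if (round(density * area) < 1) stop("population must contain >= 1 fiber",
                                      call. = FALSE)
  spec <- structure(
    list(density = density, thermo_fraction = thermo_fraction, area = area,
         class_mix = class_mix, ongoing_fraction = ongoing_fraction,
         genotype = "wildtype", t_on_range = t_on_range,
         gain_range = gain_range, ongoing_range = ongoing_range,
         cool_gain = cool_gain,
         warm_suppression_gain = warm_suppression_gain, r_max = r_max,
         noxious_cutoff = noxious_cutoff, noxious_scale = noxious_scale,
         cool_gain_scale = cool_gain_scale, seed = seed),
    class = "population_spec"
  )
  apply_genotype(spec, genotype)
}

#' Genotype lesion presets
#'
#' Returns the population-spec modifications corresponding to a genotype
#' (or pharmacological) manipulation:
#' \describe{
#'   \item{wildtype}{identity.}
#'   \item{trpm8_null, pbmc_block}{no cool-driven ongoing activity and
#'     cool-excited classes removed from the mixture (mass renormalised
#'     over the remaining classes); residual cooling gain set to 0. The
#'     pbmc preset models acute local TRPM8 antagonism and is functionally
#'     identical at the population level.}
#'   \item{trpv1_null}{warm-excited fibers keep their non-noxious gain but
#'     lose the supra-44 degC acceleration (incremental gain above 44 degC
#'     set to 0).}
#'   \item{tko}{trpv1:trpa1:trpm3 triple mutant: incremental gain above the
#'     42 degC noxious threshold reduced to 20 percent; the cool channel
#'     is intact.}
#'   \item{trpm2_null}{cool-excited class proportions halved (renormalised);
#'     warm-excited tuning unchanged.}
#' }
#'
#' @param name Preset name.
#' @return A named list of spec-field overrides (a modifier); see
#'   \code{\link{apply_genotype}}.
#' @export
genotype_preset <- function(name) {
  presets <- list(
    wildtype = list(),
    trpm8_null = list(ongoing_fraction = 0, drop_classes = COOL_CLASSES,
                      cool_gain_scale = 0),
    pbmc_block = list(ongoing_fraction = 0, drop_classes = COOL_CLASSES,
                      cool_gain_scale = 0),
    trpv1_null = list(noxious_cutoff = 44, noxious_scale = 0),
    tko = list(noxious_cutoff = 42, noxious_scale = 0.2),
    trpm2_null = list(scale_classes = stats::setNames(
      rep(0.5, length(COOL_CLASSES)), COOL_CLASSES))
  )
  if (!name %in% names(presets)) {
    stop("unknown genotype preset: ", name, call. = FALSE)
  }
  presets[[name]]
}

#' @rdname genotype_preset
#' @param spec A \code{\link{population_spec}}.
#' @return \code{apply_genotype} returns the modified spec with its
#'   \code{genotype} field set.
#' @export
apply_genotype <- function(spec, name) {
  stopifnot(inherits(spec, "population_spec"))
  mod <- genotype_preset(name)
  mix <- spec$class_mix
  if (!is.null(mod$drop_classes)) {
    mix <- mix[!names(mix) %in% mod$drop_classes]
    if (length(mix) == 0 || sum(mix) <= 0) {
      stop("genotype preset removed all fiber classes", call. = FALSE)
    }
    mix <- mix / sum(mix)
  }
  if (!is.null(mod$scale_classes)) {
    i <- intersect(names(mix), names(mod$scale_classes))
    mix[i] <- mix[i] * mod$scale_classes[i]
    mix <- mix / sum(mix)
  }
  spec$class_mix <- mix
  for (f in setdiff(names(mod), c("drop_classes", "scale_classes"))) {
    spec[[f]] <- mod[[f]]
  }
  spec$genotype <- name
  spec
}

#' Sample the fiber identities of a population
#'
#' Draws one realisation of the afferent population described by a
#' \code{\link{population_spec}}: \code{round(density * area)} fibers, of
#' which \code{round(n * thermo_fraction)} are thermosensitive; within the
#' thermosensitive subset, \code{round(n_thermo * ongoing_fraction)} are
#' tonic cool-driven fibers (classes C-MC and C-MHC in 5:1 proportion, as
#' observed) and the remainder draw class labels from \code{class_mix}.
#' Heat-responsive classes receive warm-excited tuning (t_on, gain drawn
#' from the configured ranges); cool-only classes are phasic cool-excited.
#' Non-thermosensitive fibers are mechanosensitive but thermally silent.
#'
#' @param spec A \code{\link{population_spec}}.
#' @param seed Integer seed; overrides the spec seed if given.
#' @return A data.frame of unit records, one row per fiber, with columns
#'   \code{unit_id}, \code{class_label}, \code{kind}, \code{cv},
#'   \code{responds_mech}, \code{responds_heat}, \code{responds_cold},
#'   \code{is_ongoing}, and the per-fiber tuning parameters.
#' @export
sample_population_units <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (is.null(seed)) seed <- spec$seed
  n_total <- round(spec$density * spec$area)
  n_thermo <- round(n_total * spec$thermo_fraction)
  n_tonic <- round(n_thermo * spec$ongoing_fraction)
  n_phasic <- n_thermo - n_tonic
  with_seed(if (is.null(seed)) NULL else child_seed(seed, "population"), {
    tonic_class <- if (n_tonic > 0) {
      sample(c("C-MC", "C-MHC"), n_tonic, replace = TRUE,
             prob = c(5, 1) / 6)
    } else character(0)
    phasic_class <- if (n_phasic > 0) {
      sample(names(spec$class_mix), n_phasic, replace = TRUE,
             prob = spec$class_mix)
    } else character(0)
    class_label <- c(tonic_class, phasic_class,
                     rep("non-thermo", n_total - n_thermo))
    kind <- c(
      rep("cool_tonic", n_tonic),
      ifelse(phasic_class %in% HEAT_CLASSES, "warm_excited", "cool_phasic"),
      rep("silent", n_total - n_thermo)
    )
    is_a <- startsWith(class_label, "A-")
    cv <- ifelse(is_a, stats::runif(n_total, 1.2, 10),
                 stats::runif(n_total, 0.3, 1.1))
    units <- data.frame(
      unit_id = seq_len(n_total),
      class_label = class_label,
      kind = kind,
      cv = cv,
      responds_mech = class_label != "C-C",
      responds_heat = class_label %in% HEAT_CLASSES,
      responds_cold = class_label %in% COOL_CLASSES |
        kind == "cool_tonic",
      is_ongoing = kind == "cool_tonic",
      t_on = NA_real_, gain = NA_real_, r_max = spec$r_max,
      noxious_cutoff = spec$noxious_cutoff,
      noxious_scale = spec$noxious_scale,
      ongoing_rate = 0,
      cool_gain = 0,
      warm_suppression_gain = spec$warm_suppression_gain,
      refractory = 0.005,
      stringsAsFactors = FALSE
    )
    we <- units$kind == "warm_excited"
    units$t_on[we] <- stats::runif(sum(we), spec$t_on_range[1],
                                   spec$t_on_range[2])
    units$gain[we] <- stats::runif(sum(we), spec$gain_range[1],
                                   spec$gain_range[2])
    tn <- units$kind == "cool_tonic"
    units$ongoing_rate[tn] <- stats::runif(sum(tn), spec$ongoing_range[1],
                                           spec$ongoing_range[2])
    cools <- units$kind %in% c("cool_tonic", "cool_phasic")
    units$cool_gain[cools] <- spec$cool_gain * spec$cool_gain_scale
    units
  })
}

# Per-unit instantaneous rates at a vector of temperatures: returns an
# n_temps x n_units matrix. Vectorised; the workhorse of the count-based
# population model.
unit_rate_matrix <- function(units, temps, background_temp) {
  n_t <- length(temps)
  out <- matrix(0, n_t, nrow(units))
  we <- which(units$kind == "warm_excited")
  for (i in we) {
    out[, i] <- warm_rate(temps, units$t_on[i], units$gain[i],
                          units$r_max[i], "monotonic", Inf,
                          units$noxious_cutoff[i], units$noxious_scale[i])
  }
  cl <- which(units$kind %in% c("cool_tonic", "cool_phasic"))
  if (length(cl)) {
    dwarm <- pmax(temps - background_temp, 0)
    dcool <- pmax(background_temp - temps, 0)
    for (i in cl) {
      r <- units$ongoing_rate[i] *
        pmax(1 - units$warm_suppression_gain[i] * dwarm, 0) +
        units$cool_gain[i] * dcool
      out[, i] <- pmin(r, 50)
    }
  }
  out
}

#' Simulate spike trains for a whole population
#'
#' Samples fiber identities with \code{\link{sample_population_units}} and
#' realises one spike train per fiber under the given temperature trace
#' with \code{\link{simulate_fiber}}. Each fiber receives a child seed, so
#' the result is bit-reproducible given \code{seed}.
#'
#' @param spec A \code{\link{population_spec}}.
#' @param trace A \code{\link{temperature_trace}}.
#' @param background_temp Session background temperature, degC.
#' @param seed Integer seed.
#' @return A list with \code{units} (the unit-record data.frame) and
#'   \code{trains} (a list of \code{\link{spike_train}} objects, one per
#'   unit, in unit order).
#' @export
simulate_population <- function(spec, trace, background_temp = 32,
                                seed = NULL) {
  stopifnot(inherits(trace, "temperature_trace"))
  units <- sample_population_units(spec, seed)
  trains <- lapply(seq_len(nrow(units)), function(i) {
    simulate_fiber(unit_fiber(units[i, ]), trace, background_temp,
                   seed = if (is.null(seed)) NULL
                          else child_seed(seed, paste0("fiber-", i)),
                   unit_id = units$unit_id[i])
  })
  list(units = units, trains = trains)
}

#' Reconstruct a fiber parameter object from a unit record row
#'
#' @param unit A single-row data.frame as returned by
#'   \code{\link{sample_population_units}}.
#' @return A \code{\link{fiber_params}} object, or a zero-rate tonic fiber
#'   for thermally silent units.
#' @export
unit_fiber <- function(unit) {
  stopifnot(nrow(unit) == 1L)
  if (unit$kind == "warm_excited") {
    warm_fiber(t_on = unit$t_on, gain = unit$gain, r_max = unit$r_max,
               noxious_cutoff = unit$noxious_cutoff,
               noxious_scale = unit$noxious_scale,
               class_label = unit$class_label, cv = unit$cv,
               refractory = unit$refractory)
  } else {
    tonic_fiber(ongoing_rate = unit$ongoing_rate,
                cool_gain = unit$cool_gain,
                warm_suppression_gain = unit$warm_suppression_gain,
                class_label = unit$class_label, cv = unit$cv,
                refractory = unit$refractory)
  }
}
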