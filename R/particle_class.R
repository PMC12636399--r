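#' Particle class model for the synthetic generator
#'
#' Describes one particle population by its size, shape and cargo
#' distributions. These models are synthetic stand-ins used to exercise
#' the pipeline with known truth: the shipped defaults (see
#' [default_particle_classes()]) are chosen so that EVs are larger and
#' round, NVEPs (exomeres, supermeres) smaller and more elongated, and
#' lipoprotein particles NVEP-sized but round -- the qualitative ordering
#' the analysis is expected to resolve -- without asserting any measured
#' values as ground truth.
#'
#' Distributions are given as lists: `list(type = "lognormal", meanlog =,
#' sdlog =)`, `list(type = "uniform", min =, max =)` (continuous),
#' `list(type = "uniform_int", min =, max =)` or
#' `list(type = "fixed", value =)`.
#'
#' @param class_name one of `"EV"`, `"exomere"`, `"supermere"`, `"LPP"`,
#'   `"background"` (free labels are allowed for custom mixtures).
#' @param diameter_dist distribution of particle diameter in nm
#'   (positive support).
#' @param axial_ratio_dist distribution of the major/minor axial ratio;
#'   draws are clamped at 1 (a ratio of 1 is a circle).
#' @param cargo_count_dist distribution of the number of cargo molecules
#'   per particle (labelled epitopes: tetraspanins for EVs, SNA-bound
#'   glycans for NVEPs).
#' @param labeling_efficiency probability in `[0, 1]` that a cargo
#'   molecule carries a functional probe; cargo is thinned by this
#'   before localizations are emitted.
#' @return An object of class `particle_class`.
#' @export
particle_class <- function(class_name, diameter_dist, axial_ratio_dist,
                           cargo_count_dist, labeling_efficiency = 1) {
  stopifnot(is.character(class_name), length(class_name) == 1L)
  check_number(labeling_efficiency, "labeling_efficiency", 0, 1)
  for (d in list(diameter_dist, axial_ratio_dist, cargo_count_dist)) {
    if (!is.list(d) || is.null(d$type))
      stopf("distributions must be lists with a 'type' element")
  }
  structure(list(class_name = class_name, diameter_dist = diameter_dist,
                 axial_ratio_dist = axial_ratio_dist,
                 cargo_count_dist = cargo_count_dist,
                 labeling_efficiency = labeling_efficiency),
            class = "particle_class")
}

# draw n values from a distribution spec
sample_dist <- function(dist, n) {
  if (n == 0L) return(numeric(0))
  switch(dist$type,
    lognormal   = rlnorm(n, dist$meanlog, dist$sdlog),
    uniform     = runif(n, dist$min, dist$max),
    uniform_int = sample.int(dist$max - dist$min + 1L, n, replace = TRUE) +
                    dist$min - 1L,
    fixed       = rep(dist$value, n),
    stopf("unknown distribution type '%s'", dist$type))
}

#' Default synthetic particle classes
#'
#' Synthetic population parameters (clearly labelled as such): EV
#' diameters lognormal with median 90 nm, exomeres 35 nm, supermeres
#' 25 nm, lipoprotein particles 49 nm; EVs and LPPs nearly round (axial
#' ratio ~1.1), NVEPs elongated (~1.8); EV cargo 10-40 molecules, NVEP
#' and LPP cargo 4-12. A `background` class of tiny low-cargo fragments
#' is included for clutter simulations (default mixtures use rate 0 for
#' it).
#'
#' @param labeling_efficiency labelling probability applied to all
#'   classes (default 0.9).
#' @return Named list of [particle_class()] objects.
#' @export
default_particle_classes <- function(labeling_efficiency = 0.9) {
  lgn <- function(median, sdlog)
    list(type = "lognormal", meanlog = log(median), sdlog = sdlog)
  ui <- function(a, b) list(type = "uniform_int", min = a, max = b)
  list(
    EV = particle_class("EV", lgn(90, 0.25), lgn(1.1, 0.05), ui(10, 40),
                        labeling_efficiency),
    exomere = particle_class("exomere", lgn(35, 0.15), lgn(1.8, 0.15),
                             ui(4, 12), labeling_efficiency),
    supermere = particle_class("supermere", lgn(25, 0.15), lgn(1.8, 0.15),
                               ui(4, 12), labeling_efficiency),
    LPP = particle_class("LPP", lgn(49, 0.12), lgn(1.1, 0.05), ui(4, 12),
                         labeling_efficiency),
    background = particle_class("background", lgn(15, 0.2), lgn(1.5, 0.2),
                                ui(1, 2), labeling_efficiency)
  )
}

#' Background / clutter model
#'
#' Spurious localizations not attributable to any particle: nonspecific
#' probe sticking and blinking impurities. Buffer-control fields (no
#' sample applied) are modelled as this background alone.
#'
#' @param background_loc_rate expected spurious localizations per square
#'   micrometre over the whole acquisition (>= 0). The default 0.5 gives
#'   about 840 background localizations on a standard 41 x 41 um ROI --
#'   sparse enough that controls carry minimal signal, as observed.
#' @param false_loc_sigma optional jitter (nm) applied to each background
#'   localization around its draw position; 0 leaves them exactly uniform.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(background_loc_rate = 0.5, false_loc_sigma = 0) {
  check_number(background_loc_rate, "background_loc_rate", lower = 0)
  check_number(false_loc_sigma, "false_loc_sigma", lower = 0)
  structure(list(background_loc_rate = background_loc_rate,
                 false_loc_sigma = false_loc_sigma),
            class = "noise_model")
}
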