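#' Names of the designated discriminating soil variables
#'
#' The five soil variables that the generator separates between metalliferous
#' and non-metalliferous sites: total cadmium and extractable potassium,
#' magnesium, lead and zinc. Potassium is depleted at M sites; the other four
#' are enriched, emulating the distorted nutrient supply of metalliferous
#' soils.
#'
#' @return character vector of five column names.
#' @export
designated_soil_vars <- function() {
  c("Cd_tot", "K_extr", "Mg_extr", "Pb_extr", "Zn_extr")
}

soil_var_names <- function() {
  c(designated_soil_vars(),
    "pH", "C_org", "C_tot", "N_tot", "P_Olsen", "Ca_tot",
    "Fe_tot", "Mn_tot", "Cu_tot", "S_tot", "Ni_tot")
}

climate_var_names <- function() {
  c("MeanTempAnnual", "MeanTempSummer", "MeanTempWinter",
    "MaxTempWarmestMonth", "MinTempColdestMonth", "TempSeasonality",
    "TempAnnualRange", "PrecSAnnual", "PrecSSu", "PrecSWi", "PrecSWM",
    "PrecSDM", "PrecSeasonality", "PrecSMAA", "RadiationAnnual")
}

#' Generate a per-pool environment table
#'
#' One row per pool with a site id, the binary Site-type label (1 =
#' metalliferous, 0 = non-metalliferous), 16 soil variables and 15
#' bioclimatic variables (arbitrary standardized units). The five designated
#' soil variables ([designated_soil_vars()]) are drawn from distributions
#' whose M-site mean is shifted `soil_shift_sd` within-type standard
#' deviations from the NM mean (potassium downward, the metals and magnesium
#' upward); all other variables are independent of site type.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed; defaults to the stage sub-stream of
#'   `params$seed`.
#' @return a `data.frame` with columns `site`, `Site_type`, then the 31
#'   environmental variables.
#' @export
generate_environment <- function(params, seed = split_seed(params$seed, "environment")) {
  validate_sim_params(params)
  n <- params$n_pops
  is_m <- params$site_type_labels == "M"
  with_seed(seed, {
    site <- sprintf("%s_P%02d", params$site_type_labels, seq_len(n))
    env <- data.frame(site = site,
                      Site_type = as.integer(is_m),
                      stringsAsFactors = FALSE)
    shift <- params$soil_shift_sd
    for (v in soil_var_names()) {
      base <- rnorm(n, mean = 10, sd = 1)
      if (v %in% designated_soil_vars()) {
        dir <- if (v == "K_extr") -1 else 1
        base <- base + dir * shift * as.numeric(is_m)
      }
      env[[v]] <- pmax(base, 0.01)
    }
    for (v in climate_var_names()) {
      env[[v]] <- rnorm(n, mean = 10, sd = 1)
    }
    env
  })
}

#' Generate replicate topsoil measurements around pool-level soil values
#'
#' Emulates taking several topsoil samples per site: each replicate is the
#' pool-level value of every soil variable plus independent measurement noise.
#' This is the input expected by [test_soil_discrimination()].
#'
#' @param env environment table from [generate_environment()].
#' @param n_replicates replicate samples per site (default 3).
#' @param rep_sd measurement-noise standard deviation (same units as the
#'   soil variables; default 0.5).
#' @param seed integer seed.
#' @return long `data.frame`: `site`, `Site_type`, `replicate`, soil columns.
#' @export
generate_soil_replicates <- function(env, n_replicates = 3, rep_sd = 0.5,
                                     seed = 1L) {
  if (n_replicates < 2)
    stop_invalid("need at least 2 replicate samples per site")
  vars <- intersect(soil_var_names(), names(env))
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      d <- env[, c("site", "Site_type")]
      d$replicate <- r
      for (v in vars) d[[v]] <- pmax(env[[v]] + rnorm(nrow(env), 0, rep_sd), 0.01)
      d
    }))
    rownames(out) <- NULL
    out
  })
}
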