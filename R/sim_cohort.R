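#' Cohort simulation specification
#'
#' Emulates the study's effect structure: three groups (AD, CTE, NC) of
#' five subjects with ages in the study's ranges, per-region granule
#' fields for crest and sulcus in three tissue strata (supragranular GM,
#' infragranular GM, WM), disease effects confined to the sulcus (crest
#' multipliers are 1 by construction), and a linear age trend of
#' lipofuscin load that cancels in sulcus-over-crest ratios.
#'
#' The generator has two physical dials per region, particle density and
#' radius; area-fraction effects are emergent
#' (`fraction_mult = density_mult * radius_mult^2`). The default effect
#' multipliers encode: AD sulcus-GM density x1.5; AD sulcus-WM area
#' fraction +33% (density x1.2, radius x1.053); CTE confined to the
#' infragranular sulcus GM with area fraction +27% and density +15%
#' (radius x1.051); all crest regions unchanged.
#'
#' @param n_per_group subjects per group (default 5).
#' @param ages named list of per-subject ages; defaults lie inside the
#'   study ranges (AD 76-87, CTE 75-89, NC 62-80).
#' @param baseline named list per tissue of
#'   `c(density_per_mm2, radius_mean_um, radius_sd_um)`.
#' @param effects data frame with columns group, side, tissue,
#'   density_mult, radius_mult; missing cells default to 1. Only sulcus
#'   rows are allowed: crest effects are pinned at 1.
#' @param age_slope_per_year named vector of relative density increase per
#'   year (applied around age 70) for GM and WM.
#' @param subject_sd sd of the per-subject lognormal global load scale.
#' @param field_um square per-region field side, um.
#' @param pixel_size_um pixel pitch of rendered fields.
#' @param particle_contrast peak/background ratio of rendered granules.
#' @param n_slices independent slices rendered per region (averaged
#'   downstream).
#' @param seed integer seed or NULL.
#' @return class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 5L,
                        ages = list(AD = c(76, 79, 82, 85, 87),
                                    CTE = c(75, 78, 82, 86, 89),
                                    NC = c(62, 67, 71, 76, 80)),
                        baseline = list(
                          GM_supra = c(density_per_mm2 = 400,
                                       radius_mean_um = 2.0,
                                       radius_sd_um = 0.5),
                          GM_infra = c(density_per_mm2 = 800,
                                       radius_mean_um = 1.4,
                                       radius_sd_um = 0.35),
                          WM = c(density_per_mm2 = 120,
                                 radius_mean_um = 1.2,
                                 radius_sd_um = 0.3)),
                        effects = NULL,
                        age_slope_per_year = c(GM = 0.010, WM = 0.015),
                        subject_sd = 0.15,
                        field_um = 500, pixel_size_um = 3,
                        particle_contrast = 2, n_slices = 1L,
                        seed = NULL) {
  groups <- c("AD", "CTE", "NC")
  stopifnot(all(groups %in% names(ages)))
  for (g in groups) {
    if (length(ages[[g]]) < n_per_group)
      stop("ages$", g, " must have at least n_per_group entries", call. = FALSE)
    ages[[g]] <- ages[[g]][seq_len(n_per_group)]
  }
  rng <- list(AD = c(76, 87), CTE = c(75, 89), NC = c(62, 80))
  for (g in groups)
    if (any(ages[[g]] < rng[[g]][1] | ages[[g]] > rng[[g]][2]))
      warning("ages$", g, " outside the study range ",
              rng[[g]][1], "-", rng[[g]][2])
  if (is.null(effects)) {
    effects <- data.frame(
      group = c("AD", "AD", "AD", "CTE"),
      side = "sulcus",
      tissue = c("GM_supra", "GM_infra", "WM", "GM_infra"),
      density_mult = c(1.5, 1.5, 1.2, 1.15),
      radius_mult = c(1.0, 1.0, 1.053, 1.051))
  }
  if (any(effects$side != "sulcus"))
    stop("effects may only target the sulcus; crest multipliers are 1",
         call. = FALSE)
  if (any(effects$density_mult < 0 | effects$radius_mult <= 0))
    stop("effect multipliers must be non-negative", call. = FALSE)
  structure(list(n_per_group = as.integer(n_per_group), ages = ages,
                 baseline = baseline, effects = effects,
                 age_slope_per_year = age_slope_per_year,
                 subject_sd = subject_sd, field_um = field_um,
                 pixel_size_um = pixel_size_um,
                 particle_contrast = particle_contrast,
                 n_slices = as.integer(n_slices), seed = seed),
            class = "cohort_spec")
}

effect_mult <- function(spec, group, side, tissue) {
  e <- spec$effects
  hit <- e$group == group & e$side == side & e$tissue == tissue
  if (any(hit)) c(density = e$density_mult[hit][1], radius = e$radius_mult[hit][1])
  else c(density = 1, radius = 1)
}

#' Generate a synthetic cohort with per-region ground truth
#'
#' For each subject and each (side x tissue) region, plants a granule
#' field whose expected metrics equal
#' `baseline x group multiplier x age factor x subject scale`, and records
#' those expectations in a truth table. With `render = TRUE` full images
#' are simulated (and can be segmented downstream); with `render = FALSE`
#' only the planted particle tables are produced, which is considerably
#' faster and sufficient for statistical calibration work.
#'
#' @param spec a [cohort_spec()].
#' @param sides,tissues subsets of regions to generate (defaults: all).
#' @param render simulate full images (TRUE) or particle tables only.
#' @return class `cohort`: `subjects` (data frame subject/group/age),
#'   `regions` (nested list `[[subject]][[side.tissue]]` of per-slice
#'   generator outputs), `expectations` (data frame of expected metric
#'   values per subject x region), `spec`.
#' @export
generate_cohort <- function(spec, sides = c("crest", "sulcus"),
                            tissues = c("GM_supra", "GM_infra", "WM"),
                            render = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c("AD", "CTE", "NC")
  with_seed(spec$seed, {
    subjects <- do.call(rbind, lapply(groups, function(g)
      data.frame(subject = sprintf("%s%02d", g, seq_len(spec$n_per_group)),
                 group = g, age = spec$ages[[g]][seq_len(spec$n_per_group)])))
    n_px <- round(spec$field_um / spec$pixel_size_um)
    regions <- list(); expect <- list()
    for (i in seq_len(nrow(subjects))) {
      subj <- subjects$subject[i]
      subj_scale <- rlnorm(1, 0, spec$subject_sd)
      regions[[subj]] <- list()
      for (side in sides) for (tis in tissues) {
        base <- spec$baseline[[tis]]
        mult <- effect_mult(spec, subjects$group[i], side, tis)
        slope <- spec$age_slope_per_year[[if (tis == "WM") "WM" else "GM"]]
        age_f <- max(0.2, 1 + slope * (subjects$age[i] - 70))
        dens <- base[["density_per_mm2"]] * mult[["density"]] * age_f * subj_scale
        rmean <- base[["radius_mean_um"]] * mult[["radius"]]
        rsd <- base[["radius_sd_um"]]
        slices <- lapply(seq_len(spec$n_slices), function(s) {
          gs <- granule_field_spec(
            image_shape_px = c(n_px, n_px),
            pixel_size_um = spec$pixel_size_um,
            particle_density_per_mm2 = dens,
            radius_mean_um = rmean, radius_sd_um = rsd,
            particle_contrast = spec$particle_contrast,
            count_mode = "poisson", seed = NULL)
          if (render) generate_granule_image(gs)
          else {
            a_mm2 <- (n_px * spec$pixel_size_um)^2 / 1e6
            n <- rpois(1, dens * a_mm2)
            list(truth = list(particles = data.frame(
              id = seq_len(n),
              x_um = runif(n, 0, n_px * spec$pixel_size_um),
              y_um = runif(n, 0, n_px * spec$pixel_size_um),
              radius_um = pmax(0.25, rnorm(n, rmean, rsd)),
              band = tis)), area_mm2 = a_mm2)
          }
        })
        regions[[subj]][[paste(side, tis, sep = ".")]] <- slices
        expect[[length(expect) + 1]] <- data.frame(
          subject = subj, group = subjects$group[i], side = side,
          tissue = tis,
          density_per_mm2 = dens,
          mean_radius_um = rmean,
          area_fraction_pct = 100 * dens * pi * (rmean^2 + rsd^2) / 1e6)
      }
    }
    structure(list(subjects = subjects, regions = regions,
                   expectations = do.call(rbind, expect), spec = spec),
              class = "cohort")
  })
}

#' Run segmentation and metrics over a synthetic cohort
#'
#' For rendered cohorts each region image is segmented and summarized by
#' sliding-window metric maps averaged over the whole field and over
#' slices; for unrendered cohorts the metrics are computed directly from
#' the planted particle tables. Returns the long per-region summary table
#' the statistics stage consumes.
#'
#' @param cohort a [generate_cohort()] result.
#' @param params [segmentation_params()] for rendered regions.
#' @param win [window_spec()] for rendered regions.
#' @return data frame: subject, group, age, side, tissue, metric, mean.
#' @export
analyze_cohort <- function(cohort, params = segmentation_params(),
                           win = window_spec()) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- list()
  for (i in seq_len(nrow(cohort$subjects))) {
    subj <- cohort$subjects$subject[i]
    for (rg in names(cohort$regions[[subj]])) {
      slices <- cohort$regions[[subj]][[rg]]
      if (!is.null(slices[[1]]$image)) {
        maps <- lapply(slices, function(sl) {
          seg <- segment_lipofuscin(sl$image, params)
          metric_maps(seg$mask, seg$particles, win)
        })
        agg <- aggregate_region(maps)
        means <- setNames(agg$mean, agg$metric)
      } else {
        per_slice <- vapply(slices, function(sl) {
          p <- sl$truth$particles
          c(mean_radius_um = if (nrow(p)) mean(p$radius_um) else NA_real_,
            number_density_per_mm2 = nrow(p) / sl$area_mm2,
            area_fraction_pct = 100 * sum(pi * p$radius_um^2) /
              (sl$area_mm2 * 1e6))
        }, numeric(3))
        means <- rowMeans(per_slice, na.rm = TRUE)
      }
      st <- strsplit(rg, ".", fixed = TRUE)[[1]]
      rows[[length(rows) + 1]] <- data.frame(
        subject = subj, group = cohort$subjects$group[i],
        age = cohort$subjects$age[i], side = st[1], tissue = st[2],
        metric = names(means), mean = as.numeric(means), row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
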