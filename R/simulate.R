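#' Niche archetype specification for the synthetic generator
#'
#' A niche archetype is a Gaussian blob of spatially co-clustered cells with a
#' fixed cell-type composition. The default archetypes emulate the two
#' treatment-associated niches: a responder-associated blob rich in dendritic
#' cells, cytotoxic and helper T cells with M1-like (PD-L1+) macrophages, and
#' a non-responder-associated stroma-dominated blob. The 7-marker panel
#' carries no fibroblast channel, so the stromal archetype is modelled as
#' PD-L1- macrophage / tumor dominated.
#'
#' @param name archetype name.
#' @param composition named probability vector over panel cell types
#'   (non-negative, sums to 1 within 1e-9).
#' @param blob_radius Gaussian standard deviation of member positions around
#'   the blob center, microns.
#' @param cells_per_blob expected number of member cells per blob.
#' @return object of class `niche_spec`.
#' @export
niche_spec <- function(name, composition, blob_radius = 40,
                       cells_per_blob = 150) {
  stopifnot(is.character(name), length(name) == 1L,
            blob_radius > 0, cells_per_blob > 0)
  composition <- unlist(composition)
  if (is.null(names(composition)) || any(!nzchar(names(composition))))
    stop("composition must be named by cell type")
  if (any(composition < 0)) stop("composition must be non-negative")
  if (abs(sum(composition) - 1) > 1e-9) stop("composition must sum to 1")
  structure(list(name = name, composition = composition,
                 blob_radius = blob_radius, cells_per_blob = cells_per_blob),
            class = "niche_spec")
}

#' @rdname niche_spec
#' @param panel a [tme_panel()]; compositions are checked against its types.
#' @export
default_niche_specs <- function(panel = panel_pdac7()) {
  specs <- list(
    in8_like = niche_spec("in8_like", c(
      DC = 0.25, CTL = 0.30, Th = 0.25, PDL1pos_M = 0.10,
      PDL1neg_M = 0.05, B = 0.05)),
    in3_like = niche_spec("in3_like", c(
      PDL1neg_M = 0.60, Tumor = 0.25, CTL = 0.10, B = 0.05)))
  for (s in specs)
    if (!all(names(s$composition) %in% panel$types))
      stop("composition types missing from panel for spec ", s$name)
  specs
}

# default background mixture: tumor-dominated with sparse immune infiltrate
default_background_composition <- function() {
  c(Tumor = 0.70, CTL = 0.08, Th = 0.06, PDL1neg_M = 0.05, DC = 0.04,
    B = 0.04, PDL1pos_M = 0.03)
}

#' Simulate one spatial cell map
#'
#' A homogeneous Poisson background of cells (typed from
#' `background_composition`) over an axis-aligned window, plus isotropic
#' Gaussian blobs whose member types are drawn from each archetype's
#' composition (positions truncated to the window by resampling). Ground
#' truth blob membership is attached as `attr(map, "truth")`.
#'
#' @param niche_specs list of [niche_spec()] objects.
#' @param n_blobs integer vector, blobs per archetype (recycled, same order
#'   as `niche_specs`).
#' @param background_density background intensity, cells per mm^2.
#' @param bounds window as `c(width, height)` in microns.
#' @param seed integer seed (R Mersenne-Twister; all sub-streams derived).
#' @param panel a [tme_panel()].
#' @param background_composition named probability vector over panel types.
#' @param roi_id,patient_id identifiers stamped on the generated cells.
#' @return A [cell_map()] with a `truth` attribute: data.frame of
#'   `cell_id`, `blob` (archetype name or "background") and `blob_id`.
#' @export
simulate_cell_map <- function(niche_specs, n_blobs, background_density,
                              bounds = c(1000, 1000), seed = 1L,
                              panel = panel_pdac7(),
                              background_composition = default_background_composition(),
                              roi_id = "ROI1", patient_id = "P1") {
  if (background_density <= 0) stop("background_density must be positive")
  if (length(bounds) != 2L || any(bounds <= 0)) stop("bounds must be positive")
  if (length(niche_specs) && is.null(names(niche_specs)))
    names(niche_specs) <- vapply(niche_specs, `[[`, "", "name")
  n_blobs <- rep_len(as.integer(n_blobs), length(niche_specs))
  set.seed(sub_seed(seed, "cellmap"))
  w <- bounds[1L]; h <- bounds[2L]
  area_mm2 <- w * h / 1e6
  n_bg <- stats::rpois(1L, background_density * area_mm2)
  bg_types <- if (n_bg) sample(names(background_composition), n_bg,
                               replace = TRUE, prob = background_composition)
              else character()
  x <- stats::runif(n_bg, 0, w)
  y <- stats::runif(n_bg, 0, h)
  type <- bg_types
  blob <- rep("background", n_bg)
  blob_id <- rep(NA_character_, n_bg)
  centers <- NULL
  for (k in seq_along(niche_specs)) {
    sp <- niche_specs[[k]]
    if (n_blobs[k] < 1L) next
    for (b in seq_len(n_blobs[k])) {
      cx <- stats::runif(1L, 0, w); cy <- stats::runif(1L, 0, h)
      m <- sp$cells_per_blob
      bx <- stats::rnorm(m, cx, sp$blob_radius)
      by <- stats::rnorm(m, cy, sp$blob_radius)
      bad <- which(bx < 0 | bx > w | by < 0 | by > h)
      while (length(bad)) {  # truncate to window by resampling
        bx[bad] <- stats::rnorm(length(bad), cx, sp$blob_radius)
        by[bad] <- stats::rnorm(length(bad), cy, sp$blob_radius)
        bad <- bad[bx[bad] < 0 | bx[bad] > w | by[bad] < 0 | by[bad] > h]
      }
      btypes <- sample(names(sp$composition), m, replace = TRUE,
                       prob = sp$composition)
      x <- c(x, bx); y <- c(y, by); type <- c(type, btypes)
      blob <- c(blob, rep(sp$name, m))
      blob_id <- c(blob_id, rep(sprintf("%s_%s_b%d", roi_id, sp$name, b), m))
      centers <- rbind(centers, data.frame(
        roi_id = roi_id, niche = sp$name,
        blob_id = sprintf("%s_%s_b%d", roi_id, sp$name, b),
        cx = cx, cy = cy, stringsAsFactors = FALSE))
    }
  }
  n <- length(x)
  cells <- data.frame(
    cell_id = sprintf("%s_c%d", roi_id, seq_len(n)),
    roi_id = roi_id, patient_id = patient_id,
    x = x, y = y, cell_type = type, stringsAsFactors = FALSE)
  bounds_df <- data.frame(roi_id = roi_id, xmin = 0, xmax = w,
                          ymin = 0, ymax = h, stringsAsFactors = FALSE)
  map <- cell_map(cells, panel, roi_bounds = bounds_df)
  attr(map, "truth") <- list(
    membership = data.frame(cell_id = cells$cell_id, blob = blob,
                            blob_id = blob_id, stringsAsFactors = FALSE),
    centers = centers)
  map
}

#' Cohort specification for the synthetic generator
#'
#' Declares the synthetic world: patient counts by response class, 1-3 ROIs
#' per patient, background density, expected blob counts per archetype and
#' ROI, a multiplicative enrichment of the responder-associated archetype in
#' responders (`effect_size`; 1 = null world), marker noise, and exponential
#' survival with a planted hazard ratio. Defaults emulate the imaging cohort
#' scale: 47 patients (16 responders), ~3000 background cells in a
#' 1000x1000 um window.
#'
#' @param n_responders,n_nonresponders patient counts per class.
#' @param rois_per_patient integer range `c(min, max)` of ROIs per patient.
#' @param bounds ROI window `c(width, height)`, microns.
#' @param background_density cells per mm^2.
#' @param niche_specs list of [niche_spec()]s; default [default_niche_specs()].
#' @param niche_mix_responder,niche_mix_nonresponder named expected blob
#'   counts per ROI for each archetype (Poisson rates).
#' @param effect_size multiplier applied to the responder rate of the
#'   `in8_like` archetype (first spec when no `in8_like` name); must be >= 1,
#'   1 is the null world.
#' @param noise_sd marker intensity noise standard deviation.
#' @param median_os_nonresponder,median_pfs_nonresponder exponential survival
#'   medians (months) in non-responders.
#' @param hazard_ratio hazard of non-responders relative to responders for
#'   both endpoints.
#' @param censor_range administrative censoring drawn uniform over this range
#'   (months).
#' @param seed integer master seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_responders = 16, n_nonresponders = 31,
                        rois_per_patient = c(1, 3),
                        bounds = c(1000, 1000), background_density = 3000,
                        niche_specs = default_niche_specs(),
                        niche_mix_responder = c(in8_like = 0.8, in3_like = 2),
                        niche_mix_nonresponder = c(in8_like = 0.8, in3_like = 2),
                        effect_size = 4, noise_sd = 0.5,
                        median_os_nonresponder = 6,
                        median_pfs_nonresponder = 4,
                        hazard_ratio = 2, censor_range = c(12, 36),
                        seed = 1L) {
  stopifnot(n_responders >= 1, n_nonresponders >= 1,
            length(rois_per_patient) == 2L,
            rois_per_patient[1L] >= 1,
            rois_per_patient[2L] >= rois_per_patient[1L],
            background_density > 0, effect_size >= 1, noise_sd >= 0,
            hazard_ratio > 0, length(censor_range) == 2L)
  if (is.null(names(niche_specs)))
    names(niche_specs) <- vapply(niche_specs, `[[`, "", "name")
  stopifnot(setequal(names(niche_mix_responder), names(niche_specs)),
            setequal(names(niche_mix_nonresponder), names(niche_specs)))
  enriched <- if ("in8_like" %in% names(niche_specs)) "in8_like"
              else names(niche_specs)[1L]
  structure(list(n_responders = n_responders,
                 n_nonresponders = n_nonresponders,
                 rois_per_patient = as.integer(rois_per_patient),
                 bounds = bounds, background_density = background_density,
                 niche_specs = niche_specs,
                 niche_mix_responder = niche_mix_responder[names(niche_specs)],
                 niche_mix_nonresponder = niche_mix_nonresponder[names(niche_specs)],
                 enriched = enriched,
                 effect_size = effect_size, noise_sd = noise_sd,
                 median_os_nonresponder = median_os_nonresponder,
                 median_pfs_nonresponder = median_pfs_nonresponder,
                 hazard_ratio = hazard_ratio, censor_range = censor_range,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a full synthetic cohort
#'
#' Generates per-ROI cell maps (responders receive the enriched archetype's
#' blobs at `effect_size` times the non-responder Poisson rate), a clinical
#' table (best response, exponential OS/PFS with the planted hazard ratio and
#' uniform administrative censoring, CA19-9 baseline/nadir), and a `truth`
#' record of every planted parameter.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional override of `spec$seed`.
#' @param panel a [tme_panel()].
#' @return list with elements `cell_map` (all ROIs combined), `clinical`
#'   (class `clinical_table`), `truth`.
#' @export
simulate_cohort <- function(spec, seed = spec$seed, panel = panel_pdac7()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_r <- spec$n_responders; n_n <- spec$n_nonresponders
  patients <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n_r + n_n)),
    responder = rep(c(TRUE, FALSE), c(n_r, n_n)),
    stringsAsFactors = FALSE)
  set.seed(sub_seed(seed, "cohort"))
  patients$n_rois <- sample(seq(spec$rois_per_patient[1L],
                                spec$rois_per_patient[2L]),
                            nrow(patients), replace = TRUE)

  maps <- list(); truths <- list(); blob_tab <- list(); centers <- list()
  for (p in seq_len(nrow(patients))) {
    resp <- patients$responder[p]
    mix <- if (resp) spec$niche_mix_responder else spec$niche_mix_nonresponder
    if (resp) mix[spec$enriched] <- mix[spec$enriched] * spec$effect_size
    for (r in seq_len(patients$n_rois[p])) {
      rid <- sprintf("%s_R%d", patients$patient_id[p], r)
      roi_seed <- sub_seed(seed, "roi", p * 101L + r)
      set.seed(sub_seed(roi_seed, "blobcount"))
      nb <- stats::rpois(length(mix), mix)
      m <- simulate_cell_map(spec$niche_specs, nb, spec$background_density,
                             bounds = spec$bounds, seed = roi_seed,
                             panel = panel, roi_id = rid,
                             patient_id = patients$patient_id[p])
      maps[[rid]] <- m
      truths[[rid]] <- attr(m, "truth")$membership
      centers[[rid]] <- attr(m, "truth")$centers
      blob_tab[[rid]] <- data.frame(roi_id = rid, niche = names(mix),
                                    n_blobs = nb, stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, lapply(maps, function(m) m$cells))
  bounds <- do.call(rbind, lapply(maps, function(m) m$roi_bounds))
  rownames(cells) <- rownames(bounds) <- NULL
  full_map <- cell_map(cells, panel, roi_bounds = bounds)

  clinical <- simulate_clinical(patients, spec, sub_seed(seed, "clinical"))
  truth <- list(
    patients = patients,
    membership = do.call(rbind, truths),
    blobs = do.call(rbind, blob_tab),
    centers = do.call(rbind, centers),
    spec_radius = vapply(spec$niche_specs, `[[`, 0, "blob_radius"),
    enriched = spec$enriched,
    effect_size = spec$effect_size,
    hazard_ratio = spec$hazard_ratio,
    seed = seed)
  rownames(truth$membership) <- rownames(truth$blobs) <- NULL
  list(cell_map = full_map, clinical = clinical, truth = truth)
}

simulate_clinical <- function(patients, spec, seed) {
  set.seed(seed)
  n <- nrow(patients)
  resp <- patients$responder
  best <- character(n)
  best[resp] <- sample(c("CR", "PR"), sum(resp), replace = TRUE,
                       prob = c(0.05, 0.95))
  best[!resp] <- sample(c("SD", "PD"), sum(!resp), replace = TRUE,
                        prob = c(0.85, 0.15))
  rate_os_nr <- log(2) / spec$median_os_nonresponder
  rate_pfs_nr <- log(2) / spec$median_pfs_nonresponder
  rate_os <- ifelse(resp, rate_os_nr / spec$hazard_ratio, rate_os_nr)
  rate_pfs <- ifelse(resp, rate_pfs_nr / spec$hazard_ratio, rate_pfs_nr)
  os_t <- stats::rexp(n, rate_os)
  pfs_t <- stats::rexp(n, rate_pfs)
  cens <- stats::runif(n, spec$censor_range[1L], spec$censor_range[2L])
  ca_base <- stats::rlnorm(n, log(400), 1.2)
  decline <- numeric(n)
  decline[resp] <- stats::rbeta(sum(resp), 6, 2)
  nr_idx <- which(!resp)
  decline[nr_idx[best[nr_idx] == "SD"]] <-
    stats::rbeta(sum(best[nr_idx] == "SD"), 2, 2)
  decline[nr_idx[best[nr_idx] == "PD"]] <-
    stats::runif(sum(best[nr_idx] == "PD"), -0.5, 0.2)
  validate_clinical(data.frame(
    patient_id = patients$patient_id,
    best_response = best,
    os_months = pmin(os_t, cens),
    os_event = os_t <= cens,
    pfs_months = pmin(pfs_t, cens),
    pfs_event = pfs_t <= cens,
    ca199_baseline = ca_base,
    ca199_nadir = pmax(ca_base * (1 - decline), 0.1),
    stringsAsFactors = FALSE))
}

#' Simulate marker intensities from ground-truth cell types
#'
#' Each cell receives the panel signature row of its type plus Gaussian noise
#' (sd `noise_sd`), truncated at zero. With `noise_sd = 0` intensities equal
#' the signature exactly.
#'
#' @param map a [cell_map()] whose cells carry `cell_type`.
#' @param panel a [tme_panel()] (defaults to the map's panel).
#' @param noise_sd noise standard deviation on the signature scale.
#' @param seed integer seed.
#' @param drop_type if `TRUE`, the returned map omits `cell_type` (so
#'   phenotyping is exercised blind); ground truth stays available from the
#'   input.
#' @return A `cell_map` whose cells carry one intensity column per marker.
#' @export
simulate_marker_intensities <- function(map, panel = map$panel, noise_sd = 0.5,
                                        seed = 1L, drop_type = FALSE) {
  stopifnot(inherits(map, "cell_map"))
  cells <- map$cells
  if (is.null(cells$cell_type)) stop("cells carry no ground-truth cell_type")
  bad <- setdiff(unique(cells$cell_type), rownames(panel$signature))
  if (length(bad))
    stop("cell type(s) absent from panel: ", paste(bad, collapse = ", "))
  set.seed(sub_seed(seed, "intensity"))
  base <- panel$signature[cells$cell_type, , drop = FALSE]
  noise <- matrix(stats::rnorm(length(base), 0, noise_sd),
                  nrow = nrow(base))
  intens <- pmax(base + noise, 0)
  colnames(intens) <- panel$markers
  out <- cells
  for (m in panel$markers) out[[m]] <- intens[, m]
  if (drop_type) out$cell_type <- NULL
  res <- cell_map(out, panel, roi_bounds = map$roi_bounds)
  attr(res, "truth") <- attr(map, "truth")
  res
}

#' Spatial ground-truth niche labels for a simulated cohort
#'
#' The generator's process labels ("blob member" vs "background") are not the
#' right recovery target: a background-process cell lying inside a blob's
#' footprint genuinely belongs to that niche spatially. This helper labels
#' every cell with the archetype of the nearest planted blob center within
#' `radius_factor` blob radii, else "background", giving the partition a
#' niche-recovery ARI should be computed against.
#'
#' @param sim a [simulate_cohort()] result.
#' @param radius_factor footprint radius in blob-radius (SD) units
#'   (default 2).
#' @return character vector of labels, one per cell of `sim$cell_map`.
#' @export
planted_niche_truth <- function(sim, radius_factor = 2) {
  cells <- sim$cell_map$cells
  bc <- sim$truth$centers
  truth <- rep("background", nrow(cells))
  if (is.null(bc) || !nrow(bc)) return(truth)
  bc$radius <- sim$truth$spec_radius[bc$niche]
  for (r in unique(cells$roi_id)) {
    ci <- which(cells$roi_id == r)
    bi <- which(bc$roi_id == r)
    if (!length(bi)) next
    d2 <- outer(cells$x[ci], bc$cx[bi], "-")^2 +
      outer(cells$y[ci], bc$cy[bi], "-")^2
    j <- max.col(-d2, ties.method = "first")
    dm <- sqrt(d2[cbind(seq_along(ci), j)])
    lim <- radius_factor * bc$radius[bi][j]
    truth[ci][dm <= lim] <- bc$niche[bi][j][dm <= lim]
  }
  truth
}
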