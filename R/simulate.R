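#' Configuration for the single-cell expression simulator
#'
#' Defaults describe a small but realistic droplet-style experiment: 300
#' cells over 3 samples, 2000 genes, 50 signature genes per state, a
#' log-scale state effect of 1 (signature genes e-fold up in their own
#' state), mean library size 5000 counts, and mild negative-binomial
#' overdispersion (0.1).
#'
#' @param n_cells,n_genes,n_samples positive integers.
#' @param state_fractions named proportions over `OPC`, `OC`, `AC`,
#'   summing to 1.
#' @param n_signature_genes_per_state signature genes per state; three
#'   times this must not exceed `n_genes`.
#' @param state_effect log-scale mean shift of signature genes in cells
#'   of their state (dimensionless).
#' @param library_size_mean mean total counts per cell.
#' @param noise_dispersion negative-binomial dispersion; 0 gives Poisson.
#' @param coupled_gene_state state name whose shift the designated
#'   "receptor" gene shares, or `NULL` for no coupled gene.
#' @param seed integer RNG seed.
#' @return a validated list of class `ScSimConfig`.
#' @export
sc_sim_config <- function(n_cells = 300, n_genes = 2000, n_samples = 3,
                          state_fractions = c(OPC = 0.4, OC = 0.3, AC = 0.3),
                          n_signature_genes_per_state = 50,
                          state_effect = 1.0,
                          library_size_mean = 5000,
                          noise_dispersion = 0.1,
                          coupled_gene_state = "OPC",
                          seed = 1L) {
  assert_that(is_count(n_cells) && is_count(n_genes) && is_count(n_samples),
              "n_cells, n_genes, n_samples must be positive integers")
  assert_that(setequal(names(state_fractions), c("OPC", "OC", "AC")) &&
                abs(sum(state_fractions) - 1) <= 1e-9 &&
                all(state_fractions >= 0),
              "state_fractions must be named OPC/OC/AC proportions summing to 1")
  assert_that(is_count(n_signature_genes_per_state) &&
                3 * n_signature_genes_per_state <= n_genes,
              "need 3 * n_signature_genes_per_state <= n_genes")
  assert_that(is_number(state_effect), "state_effect must be a number")
  assert_that(is_number(library_size_mean) && library_size_mean > 0,
              "library_size_mean must be > 0")
  assert_that(is_number(noise_dispersion) && noise_dispersion >= 0,
              "noise_dispersion must be >= 0")
  if (!is.null(coupled_gene_state)) {
    assert_that(coupled_gene_state %in% c("OPC", "OC", "AC"),
                "coupled_gene_state must be one of OPC/OC/AC")
  }
  structure(list(n_cells = n_cells, n_genes = n_genes, n_samples = n_samples,
                 state_fractions = state_fractions[c("OPC", "OC", "AC")],
                 n_signature_genes_per_state = n_signature_genes_per_state,
                 state_effect = state_effect,
                 library_size_mean = library_size_mean,
                 noise_dispersion = noise_dispersion,
                 coupled_gene_state = coupled_gene_state,
                 seed = as.integer(seed)),
            class = "ScSimConfig")
}

#' Simulate a three-state single-cell count matrix
#'
#' Draws a gene x cell count matrix from a negative-binomial model (Poisson
#' in the zero-dispersion limit) in which each state's signature genes have
#' their mean multiplied by `exp(state_effect)` in cells of that state.
#' Baseline gene abundances are log-normal; per-cell expected totals equal
#' the mean library size. A designated "receptor" gene (`RCPT1`), when
#' `coupled_gene_state` is set, shares that state's shift without being
#' part of any signature. Cells are assigned to samples round-robin so
#' every sample contains all states; state labels are drawn once (seeded)
#' in the stated proportions.
#'
#' @param config an [sc_sim_config()].
#' @return list with `matrix` (an [expression_matrix()] of counts, all
#'   cells malignant, platform `"umi"`), `true_state` (factor per cell),
#'   `signatures` (list OPC/OC/AC of gene ids), `receptor_gene` (id or
#'   `NULL`).
#' @export
gen_expression <- function(config) {
  assert_that(inherits(config, "ScSimConfig"),
              "config must come from sc_sim_config()")
  with_seed(config$seed, {
    ng <- config$n_genes
    nc <- config$n_cells
    ns <- config$n_signature_genes_per_state
    gene_names <- sprintf("gene%05d", seq_len(ng))
    sigs <- list(OPC = gene_names[seq_len(ns)],
                 OC = gene_names[ns + seq_len(ns)],
                 AC = gene_names[2 * ns + seq_len(ns)])
    receptor <- NULL
    if (!is.null(config$coupled_gene_state)) {
      receptor <- gene_names[3 * ns + 1]
      assert_that(3 * ns + 1 <= ng,
                  "no gene left for the coupled receptor gene")
    }
    # state labels in stated proportions, randomly interleaved
    counts <- floor(config$state_fractions * nc)
    rem <- nc - sum(counts)
    if (rem > 0) {
      top <- order(config$state_fractions * nc - counts, decreasing = TRUE)
      counts[top[seq_len(rem)]] <- counts[top[seq_len(rem)]] + 1
    }
    states <- sample(rep(names(counts), counts))
    sample_of_cell <- paste0("sample", (seq_len(nc) - 1) %% config$n_samples + 1)
    # baseline abundances and per-state multipliers
    w <- exp(rnorm(ng, mean = 0, sd = 1))
    names(w) <- gene_names
    shift <- exp(config$state_effect)
    mult <- matrix(1, ng, 3, dimnames = list(gene_names, c("OPC", "OC", "AC")))
    for (st in c("OPC", "OC", "AC")) mult[sigs[[st]], st] <- shift
    if (!is.null(receptor)) mult[receptor, config$coupled_gene_state] <- shift
    vals <- matrix(0, ng, nc,
                   dimnames = list(gene_names,
                                   sprintf("cell%05d", seq_len(nc))))
    for (i in seq_len(nc)) {
      lam <- w * mult[, states[i]]
      mu <- config$library_size_mean * lam / sum(lam)
      vals[, i] <- if (config$noise_dispersion == 0) {
        rpois(ng, mu)
      } else {
        rnbinom(ng, size = 1 / config$noise_dispersion, mu = mu)
      }
    }
    m <- expression_matrix(
      vals, sample_of_cell = sample_of_cell,
      platform_of_sample = setNames(rep("umi", config$n_samples),
                                    paste0("sample", seq_len(config$n_samples))),
      unit = "counts")
    list(matrix = m,
         true_state = factor(states, levels = c("OPC", "OC", "AC")),
         signatures = sigs, receptor_gene = receptor, config = config)
  })
}

#' Configuration for the photometry trace simulator
#'
#' Defaults emulate a 10-minute recording at 20 Hz with a
#' mono-exponential bleach (amplitude 5, time constant 60 s, offset 1 in
#' fluorescence units), transient events of amplitude 1 decaying with a
#' 2 s time constant, and Gaussian noise (sd 0.05).
#'
#' @param duration recording length in seconds.
#' @param fs sampling rate in Hz.
#' @param bleach_model `"mono"` or `"bi"`.
#' @param bleach_params named list/vector: `A`, `tau`, `C` for mono;
#'   `A1`, `tau1`, `A2`, `tau2`, `C` for bi (time constants in seconds).
#' @param event_times event onset times (seconds) within the recording.
#' @param event_amplitude fluorescence amplitude of each event.
#' @param event_tau event decay time constant (seconds).
#' @param noise_sd Gaussian noise sd (fluorescence units).
#' @param seed integer RNG seed.
#' @return a validated list of class `PhotoSimConfig`.
#' @export
photo_sim_config <- function(duration = 600, fs = 20,
                             bleach_model = c("mono", "bi"),
                             bleach_params = c(A = 5, tau = 60, C = 1),
                             event_times = numeric(0),
                             event_amplitude = 1, event_tau = 2,
                             noise_sd = 0.05, seed = 1L) {
  bleach_model <- match.arg(bleach_model)
  assert_that(is_number(duration) && duration > 0, "duration must be > 0")
  assert_that(is_number(fs) && fs > 0, "fs must be > 0")
  bleach_params <- unlist(bleach_params)
  need <- if (bleach_model == "mono") c("A", "tau", "C")
          else c("A1", "tau1", "A2", "tau2", "C")
  assert_that(all(need %in% names(bleach_params)),
              "bleach_params must contain: ", paste(need, collapse = ", "))
  taus <- bleach_params[grep("^tau", names(bleach_params))]
  assert_that(all(taus > 0), "bleach time constants must be > 0")
  assert_that(all(event_times >= 0 & event_times <= duration),
              "event_times must lie in [0, duration]")
  assert_that(is_number(event_tau) && event_tau > 0, "event_tau must be > 0")
  assert_that(is_number(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  structure(list(duration = duration, fs = fs, bleach_model = bleach_model,
                 bleach_params = bleach_params[need],
                 event_times = as.numeric(event_times),
                 event_amplitude = event_amplitude, event_tau = event_tau,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "PhotoSimConfig")
}

#' Simulate a fiber-photometry trace
#'
#' Builds `trace = bleach(t) + sum of event kernels + noise`, where each
#' event has an instantaneous rise at its onset and a single-exponential
#' decay (`A * exp(-(t - t_e)/tau_e)` for `t >= t_e`), and the noise is
#' i.i.d. Gaussian. The returned ground truth includes the analytic
#' integral of each event over the remainder of the recording,
#' `A * tau_e * (1 - exp(-T/tau_e))` with `T` the time left after onset.
#'
#' @param config a [photo_sim_config()].
#' @return list with `trace` (a [photometry_trace()]) and `truth` (bleach
#'   model and parameters, event times/amplitude/tau, per-event analytic
#'   integrals `event_auc`, `noise_sd`).
#' @export
gen_photometry <- function(config) {
  assert_that(inherits(config, "PhotoSimConfig"),
              "config must come from photo_sim_config()")
  n <- floor(config$duration * config$fs) + 1
  t <- (seq_len(n) - 1) / config$fs
  p <- as.list(config$bleach_params)
  bleach <- if (config$bleach_model == "mono") {
    p$A * exp(-t / p$tau) + p$C
  } else {
    p$A1 * exp(-t / p$tau1) + p$A2 * exp(-t / p$tau2) + p$C
  }
  events <- rep(0, n)
  for (te in config$event_times) {
    on <- t >= te
    events[on] <- events[on] +
      config$event_amplitude * exp(-(t[on] - te) / config$event_tau)
  }
  noise <- if (config$noise_sd > 0) {
    with_seed(config$seed, rnorm(n, 0, config$noise_sd))
  } else rep(0, n)
  tr <- photometry_trace(t, bleach + events + noise, fs = config$fs)
  t_left <- config$duration - config$event_times
  truth <- list(bleach_model = config$bleach_model,
                bleach_params = config$bleach_params,
                event_times = config$event_times,
                event_amplitude = config$event_amplitude,
                event_tau = config$event_tau,
                event_auc = config$event_amplitude * config$event_tau *
                  (1 - exp(-t_left / config$event_tau)),
                noise_sd = config$noise_sd)
  list(trace = tr, truth = truth)
}

#' Configuration for the puncta field simulator
#'
#' Defaults describe a 20 x 20 x 5 um field with 150 presynaptic
#' (neuron) and 100 postsynaptic (glioma) puncta, 40% of the glioma
#' puncta truly colocalized with a 0.2 um placement jitter, confocal-like
#' anisotropic voxels (0.15 um z, 0.1 um in plane), 0.3 um blobs and a
#' peak SNR of 10 for rendered stacks.
#'
#' @param volume `(x, y, z)` extents in micrometers.
#' @param n_neuron_puncta,n_glioma_puncta point counts per channel.
#' @param colocalized_fraction fraction of glioma puncta placed next to a
#'   neuron punctum, in \[0, 1\].
#' @param coloc_distance_sd isotropic Gaussian displacement sd (um) of
#'   colocalized placements.
#' @param voxel_size `(dz, dy, dx)` in micrometers (for rendering).
#' @param blob_sigma rendered blob scale in micrometers.
#' @param peak_snr rendered blob peak amplitude over noise sd.
#' @param seed integer RNG seed.
#' @return a validated list of class `PunctaSimConfig`.
#' @export
puncta_sim_config <- function(volume = c(20, 20, 5),
                              n_neuron_puncta = 150, n_glioma_puncta = 100,
                              colocalized_fraction = 0.4,
                              coloc_distance_sd = 0.2,
                              voxel_size = c(0.15, 0.1, 0.1),
                              blob_sigma = 0.3, peak_snr = 10, seed = 1L) {
  assert_that(length(volume) == 3 && all(volume > 0),
              "volume must be three positive extents (x, y, z)")
  assert_that(is_count(n_neuron_puncta) && is_count(n_glioma_puncta),
              "puncta counts must be positive integers")
  assert_that(is_number(colocalized_fraction) &&
                colocalized_fraction >= 0 && colocalized_fraction <= 1,
              "colocalized_fraction must lie in [0, 1]")
  assert_that(is_number(coloc_distance_sd) && coloc_distance_sd >= 0,
              "coloc_distance_sd must be >= 0")
  assert_that(length(voxel_size) == 3 && all(voxel_size > 0),
              "voxel_size must be three positive numbers (dz, dy, dx)")
  assert_that(is_number(blob_sigma) && blob_sigma > 0, "blob_sigma must be > 0")
  assert_that(all(volume > 4 * blob_sigma),
              "volume extents must exceed 4 * blob_sigma")
  structure(list(volume = as.numeric(volume),
                 n_neuron_puncta = n_neuron_puncta,
                 n_glioma_puncta = n_glioma_puncta,
                 colocalized_fraction = colocalized_fraction,
                 coloc_distance_sd = coloc_distance_sd,
                 voxel_size = as.numeric(voxel_size),
                 blob_sigma = blob_sigma, peak_snr = peak_snr,
                 seed = as.integer(seed)),
            class = "PunctaSimConfig")
}

#' Simulate a two-channel puncta field with known colocalization
#'
#' Neuron (presynaptic) puncta are placed uniformly in the volume. A
#' `colocalized_fraction` of glioma (postsynaptic) puncta are placed at a
#' randomly chosen neuron punctum plus an isotropic Gaussian displacement
#' (sd `coloc_distance_sd`, clamped to the volume); the remainder are
#' uniform. When `render = TRUE` the two channels are additionally
#' rendered as Gaussian-blob image stacks: flat background, blob peak
#' amplitude `peak_snr` times the Gaussian noise sd.
#'
#' @param config a [puncta_sim_config()].
#' @param render also return rendered `ImageStack`s (default `FALSE`).
#' @return list with `neuron` and `glioma` ([puncta_set()]s),
#'   `is_colocalized` (logical ground truth per glioma punctum), and,
#'   when rendered, `stack_neuron`, `stack_glioma`.
#' @export
gen_puncta <- function(config, render = FALSE) {
  assert_that(inherits(config, "PunctaSimConfig"),
              "config must come from puncta_sim_config()")
  with_seed(config$seed, {
    vol <- config$volume
    runif3 <- function(n) cbind(x_um = runif(n, 0, vol[1]),
                                y_um = runif(n, 0, vol[2]),
                                z_um = runif(n, 0, vol[3]))
    neuron <- runif3(config$n_neuron_puncta)
    n_co <- round(config$colocalized_fraction * config$n_glioma_puncta)
    n_free <- config$n_glioma_puncta - n_co
    co <- matrix(numeric(0), 0, 3)
    if (n_co > 0) {
      anchors <- neuron[sample.int(nrow(neuron), n_co, replace = TRUE), ,
                        drop = FALSE]
      disp <- matrix(rnorm(3 * n_co, 0, config$coloc_distance_sd), n_co, 3)
      co <- anchors + disp
      co <- pmin(pmax(co, 0), matrix(vol, n_co, 3, byrow = TRUE))
    }
    glioma <- rbind(co, runif3(n_free))
    colnames(glioma) <- c("x_um", "y_um", "z_um")
    is_co <- c(rep(TRUE, n_co), rep(FALSE, n_free))
    # shuffle so colocalized puncta are not a prefix
    perm <- sample.int(nrow(glioma))
    out <- list(neuron = puncta_set(neuron, channel = "presynaptic"),
                glioma = puncta_set(glioma[perm, , drop = FALSE],
                                    channel = "postsynaptic"),
                is_colocalized = is_co[perm],
                config = config)
    if (render) {
      out$stack_neuron <- render_puncta_stack(out$neuron, config)
      out$stack_glioma <- render_puncta_stack(out$glioma, config)
    }
    out
  })
}

#' Render a puncta set as a Gaussian-blob image stack
#'
#' Each punctum becomes an isotropic (in physical units) Gaussian blob of
#' scale `blob_sigma` and peak amplitude `peak_snr * noise_sd` on a flat
#' background of one noise sd, plus Gaussian noise (sd 1 intensity unit),
#' clipped at zero. No microscope PSF beyond the Gaussian blob is
#' emulated. Uses the RNG ambient state; call inside a seeded context for
#' reproducibility ([gen_puncta()] does).
#'
#' @param pset a [puncta_set()].
#' @param config a [puncta_sim_config()] providing volume, voxel size,
#'   blob scale and SNR.
#' @return an [image_stack()].
#' @export
render_puncta_stack <- function(pset, config) {
  vox <- config$voxel_size                        # (dz, dy, dx)
  dims <- c(ceiling(config$volume[3] / vox[1]),   # z planes
            ceiling(config$volume[2] / vox[2]),   # y rows
            ceiling(config$volume[1] / vox[3]))   # x cols
  noise_sd <- 1
  amp <- config$peak_snr * noise_sd
  arr <- array(rnorm(prod(dims), mean = noise_sd, sd = noise_sd), dims)
  sig_px <- config$blob_sigma / vox               # per-axis sigma in voxels
  half <- ceiling(3 * sig_px)
  for (i in seq_len(nrow(pset$coords))) {
    # physical coordinate -> fractional voxel index (voxel centers at
    # (j - 0.5) * voxel)
    ctr <- c(pset$coords[i, "z_um"] / vox[1],
             pset$coords[i, "y_um"] / vox[2],
             pset$coords[i, "x_um"] / vox[3]) + 0.5
    rng <- lapply(1:3, function(a) {
      max(1, floor(ctr[a] - half[a])):min(dims[a], ceiling(ctr[a] + half[a]))
    })
    gz <- exp(-(rng[[1]] - ctr[1])^2 / (2 * sig_px[1]^2))
    gy <- exp(-(rng[[2]] - ctr[2])^2 / (2 * sig_px[2]^2))
    gx <- exp(-(rng[[3]] - ctr[3])^2 / (2 * sig_px[3]^2))
    arr[rng[[1]], rng[[2]], rng[[3]]] <-
      arr[rng[[1]], rng[[2]], rng[[3]]] + amp * (gz %o% gy %o% gx)
  }
  image_stack(pmax(arr, 0), voxel_size = vox, channel = pset$channel)
}

#' Simulate per-cell marker records for proliferation assays
#'
#' Generates a cell-record table over `n_fields` imaging fields of
#' `cells_per_field` cells each; every cell is positive for the
#' denominator markers (DAPI, HNA, GFP) and EdU-positive with probability
#' `p_edu` (Bernoulli, seeded).
#'
#' @param n_fields,cells_per_field positive integers.
#' @param p_edu EdU labeling probability in \[0, 1\].
#' @param seed integer RNG seed.
#' @param group_id group label for all fields (default `"group1"`).
#' @return `data.frame` with columns `cell_id`, `field_id`, `group_id`,
#'   `EdU`, `DAPI`, `HNA`, `GFP`.
#' @export
gen_cell_records <- function(n_fields, cells_per_field, p_edu, seed = 1L,
                             group_id = "group1") {
  assert_that(is_count(n_fields) && is_count(cells_per_field),
              "n_fields and cells_per_field must be positive integers")
  assert_that(is_number(p_edu) && p_edu >= 0 && p_edu <= 1,
              "p_edu must lie in [0, 1]")
  n <- n_fields * cells_per_field
  with_seed(seed, {
    data.frame(
      cell_id = sprintf("cell%06d", seq_len(n)),
      field_id = rep(sprintf("field%02d", seq_len(n_fields)),
                     each = cells_per_field),
      group_id = group_id,
      EdU = runif(n) < p_edu,
      DAPI = TRUE, HNA = TRUE, GFP = TRUE,
      stringsAsFactors = FALSE)
  })
}
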