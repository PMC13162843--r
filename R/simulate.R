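#' Configuration for synthetic repertoire generation
#'
#' Parameters of the synthetic longitudinal TCR-beta repertoire generator.
#' Defaults emulate a deep-level bulk blood survey: a heavy-tailed clone-size
#' law over 50,000 clonotypes sampled at 200,000 templates per draw. The
#' power-law default (Pareto tail index 2 on clone sizes) was calibrated so
#' that baseline Simpson clonality falls inside the range observed in real
#' deep blood repertoires (roughly 0.004-0.22); sequencing depth and
#' repertoire size are configurable because real per-sample values vary.
#'
#' @param n_clones Number of clonotypes in the true baseline repertoire.
#' @param clone_distribution `"power_law"` (clone sizes `U^(-1/alpha)`,
#'   Pareto with tail index `power_exponent`) or `"log_normal"` (sizes
#'   `exp(N(lnorm_meanlog, lnorm_sdlog))`).
#' @param power_exponent Pareto tail index of the power-law sizes (> 0).
#' @param lnorm_meanlog,lnorm_sdlog Log-normal size parameters.
#' @param depth Templates sampled per blood draw.
#' @param drift_sigma Standard deviation of the log-normal multiplicative
#'   perturbation applied to true frequencies between draws (0 = no
#'   biological drift, pure sampling noise).
#' @param n_new_events,n_increase_events Number of planted expansion events
#'   per follow-up (truly new clones / truly increased clones).
#' @param fold_range True frequency fold-change range for planted increases
#'   (uniform; default 10-100).
#' @param new_freq_range True follow-up frequency range for planted new
#'   clones (uniform; default 0.05%-0.2%, comfortably detectable at the
#'   default depth).
#' @param increase_baseline_range True baseline frequency band from which
#'   planted-increase clones are drawn (default 0.01%-0.1%, so the baseline
#'   is reliably detected).
#' @param biopsy_shared_fraction Fraction of baseline blood clones also
#'   present in the tumor biopsy.
#' @param biopsy_depth Templates sampled in the biopsy.
#' @param followup_days Integer days of the follow-up blood draws.
#' @param baseline_day Integer day of the pre-procedure draw (<= 0).
#' @param seed Integer seed; identical configurations generate bit-identical
#'   data.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_clones = 5e4,
                              clone_distribution = c("power_law", "log_normal"),
                              power_exponent = 2,
                              lnorm_meanlog = 0, lnorm_sdlog = 3,
                              depth = 2e5,
                              drift_sigma = 0,
                              n_new_events = 0,
                              n_increase_events = 0,
                              fold_range = c(10, 100),
                              new_freq_range = c(5e-4, 2e-3),
                              increase_baseline_range = c(1e-4, 1e-3),
                              biopsy_shared_fraction = 0.3,
                              biopsy_depth = 5e4,
                              followup_days = c(30L, 90L),
                              baseline_day = -7L,
                              seed = 1L) {
  clone_distribution <- match.arg(clone_distribution)
  if (n_clones < 1 || n_clones != round(n_clones)) {
    abort("`n_clones` must be a positive integer.",
      class = "clonotrack_value_error")
  }
  if (power_exponent <= 0 || lnorm_sdlog < 0 || depth < 0 ||
      drift_sigma < 0 || biopsy_depth < 0) {
    abort("Distribution, depth and drift parameters must be non-negative (exponent positive).",
      class = "clonotrack_value_error")
  }
  if (biopsy_shared_fraction < 0 || biopsy_shared_fraction > 1) {
    abort("`biopsy_shared_fraction` must lie in [0, 1].",
      class = "clonotrack_value_error")
  }
  if (n_new_events < 0 || n_increase_events < 0) {
    abort("Event counts must be non-negative.",
      class = "clonotrack_value_error")
  }
  structure(as.list(environment()), class = "simulation_config")
}

#' Generate a true baseline repertoire
#'
#' Draws clone sizes from the configured heavy-tailed law and normalises
#' them into a true frequency vector; clonotype identities are synthetic id
#' strings (no V(D)J sequence realism is attempted).
#'
#' @param config A [simulation_config()].
#' @return A tibble `rearrangement`, `true_freq` (summing to 1),
#'   deterministic given `config$seed`.
#' @export
generate_baseline <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    w <- switch(config$clone_distribution,
      power_law = runif(config$n_clones)^(-1 / config$power_exponent),
      log_normal = exp(rnorm(config$n_clones, config$lnorm_meanlog,
        config$lnorm_sdlog))
    )
    tibble(
      rearrangement = sprintf("SYN%07d", seq_len(config$n_clones)),
      true_freq = w / sum(w)
    )
  })
}

#' Multinomial template sampling
#'
#' Draws the observed template counts of one sequencing run: a single
#' multinomial draw of `depth` templates over the true clone frequencies,
#' so per-sample totals are exact and observed frequencies comparable
#' across samples.
#'
#' @param true_freqs Numeric frequency vector summing to 1.
#' @param depth Total templates to draw.
#' @param seed Optional integer seed (uses and restores the RNG state when
#'   given).
#' @return An integer count vector along `true_freqs`, summing to `depth`.
#' @export
sample_counts <- function(true_freqs, depth, seed = NULL) {
  if (abs(sum(true_freqs) - 1) > 1e-9) {
    abort("`true_freqs` must sum to 1.", class = "clonotrack_value_error")
  }
  if (depth == 0) return(integer(length(true_freqs)))
  draw <- function() as.integer(rmultinom(1, size = depth, prob = true_freqs))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Apply between-draw biological drift
#'
#' Multiplies each true frequency by an independent log-normal(0, sigma)
#' factor and renormalises — the model for the baseline fluctuation of the
#' T-cell repertoire between two draws with no intervening treatment, which
#' is what makes naive per-clone tests over-call expansions on
#' negative-control pairs.
#'
#' @param true_freqs Numeric frequency vector summing to 1.
#' @param drift_sigma Non-negative log-scale standard deviation; 0 is the
#'   identity.
#' @param seed Optional integer seed.
#' @return A perturbed frequency vector summing to 1.
#' @export
apply_drift <- function(true_freqs, drift_sigma, seed = NULL) {
  if (drift_sigma < 0) {
    abort("`drift_sigma` must be non-negative.",
      class = "clonotrack_value_error")
  }
  if (drift_sigma == 0) return(true_freqs)
  perturb <- function() {
    w <- true_freqs * exp(rnorm(length(true_freqs), 0, drift_sigma))
    w / sum(w)
  }
  if (is.null(seed)) perturb() else withr::with_seed(seed, perturb())
}

#' Plant ground-truth expansion events
#'
#' Produces the true follow-up repertoire from a true baseline by planting
#' expansion events with recorded ground truth: planted **new** clones are
#' genuinely absent from the true baseline (not merely unsampled) and
#' appear at a true follow-up frequency drawn from
#' `config$new_freq_range`; planted **increased** clones are drawn from the
#' baseline band `config$increase_baseline_range` and rise by an exact true
#' fold drawn from `config$fold_range`. Untouched clones are scaled to fill
#' the remaining probability mass, so planted frequencies and folds hold
#' exactly.
#'
#' @param baseline A `rearrangement`/`true_freq` tibble from
#'   [generate_baseline()].
#' @param config A [simulation_config()] (uses the event fields and
#'   `seed`).
#' @param seed Optional override of `config$seed`.
#' @return A list:
#'   * `baseline` — the input with planted new clones appended at
#'     `true_freq = 0`;
#'   * `followup` — tibble `rearrangement`, `true_freq` of the true
#'     follow-up repertoire;
#'   * `truth` — list with `planted_new`, `planted_increased` (disjoint id
#'     sets) and `events`, a tibble of per-event true frequencies and
#'     folds.
#' @export
spike_expansions <- function(baseline, config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- seed %||% config$seed
  n_new <- config$n_new_events
  n_inc <- config$n_increase_events
  withr::with_seed(seed, {
    candidates <- which(
      baseline$true_freq >= config$increase_baseline_range[1] &
        baseline$true_freq <= config$increase_baseline_range[2]
    )
    if (length(candidates) < n_inc) {
      abort(sprintf(
        "Only %d clones lie in the increase baseline band; cannot plant %d increase events.",
        length(candidates), n_inc
      ), class = "clonotrack_value_error")
    }
    inc_idx <- if (n_inc > 0) sample(candidates, n_inc) else integer()
    folds <- runif(n_inc, config$fold_range[1], config$fold_range[2])
    new_freqs <- runif(n_new, config$new_freq_range[1],
      config$new_freq_range[2])
    new_ids <- if (n_new > 0) {
      sprintf("SYNNEW%05d", seq_len(n_new))
    } else {
      character()
    }

    base_out <- bind_rows(
      baseline,
      tibble(rearrangement = new_ids, true_freq = 0)
    )

    fu_freq <- c(baseline$true_freq, rep(0, n_new))
    planted_idx <- c(inc_idx, length(baseline$true_freq) + seq_len(n_new))
    planted_val <- c(baseline$true_freq[inc_idx] * folds, new_freqs)
    if (sum(planted_val) >= 1) {
      abort("Planted events exceed the available probability mass.",
        class = "clonotrack_value_error")
    }
    free_mass <- sum(fu_freq[-planted_idx])
    if (length(planted_idx) > 0) {
      fu_freq[-planted_idx] <- fu_freq[-planted_idx] *
        (1 - sum(planted_val)) / free_mass
      fu_freq[planted_idx] <- planted_val
    }

    list(
      baseline = base_out,
      followup = tibble(rearrangement = base_out$rearrangement,
        true_freq = fu_freq),
      truth = list(
        planted_new = new_ids,
        planted_increased = baseline$rearrangement[inc_idx],
        events = tibble(
          rearrangement = c(baseline$rearrangement[inc_idx], new_ids),
          kind = c(rep("increased", n_inc), rep("new", n_new)),
          baseline_true_freq = c(baseline$true_freq[inc_idx],
            rep(0, n_new)),
          followup_true_freq = planted_val,
          true_fold = c(folds, rep(NA_real_, n_new))
        )
      )
    )
  })
}

# Assemble an observed repertoire tibble (clonotype-table shape) from true
# frequencies: multinomial draw, zero-count clones dropped as undetected.
observe_sample <- function(freq_tbl, depth, sample_id, subject_id,
                           compartment, timepoint_days, seed) {
  counts <- sample_counts(freq_tbl$true_freq, depth, seed = seed)
  keep <- counts > 0
  tibble(
    sample_id = sample_id,
    subject_id = subject_id,
    compartment = compartment,
    timepoint_days = as.integer(timepoint_days),
    rearrangement = freq_tbl$rearrangement[keep],
    cdr3_aa = NA_character_,
    v_gene = "unresolved",
    j_gene = "unresolved",
    status = "productive",
    templates = counts[keep]
  )
}

#' Generate a synthetic longitudinal cohort with ground truth
#'
#' End-to-end fixture generator: for each synthetic patient, a true
#' heavy-tailed baseline repertoire, planted expansion events
#' ([spike_expansions()]), optional between-draw drift ([apply_drift()]),
#' multinomial sequencing of the pre-procedure and follow-up blood draws
#' ([sample_counts()]), and optionally a tumor biopsy sharing
#' `biopsy_shared_fraction` of the baseline blood clones. Identical
#' configuration and seed give bit-identical output.
#'
#' @param config A [simulation_config()] applied to every patient; patient
#'   `i` uses seed `config$seed + 1000 * i`.
#' @param n_patients Number of patients.
#' @param biopsy Logical vector (recycled) saying which patients get a
#'   biopsy sample.
#' @param out_dir Optional directory: per-sample immunoseq-dialect TSVs, a
#'   `manifest.json` (per-subject files, compartments, timepoints) and a
#'   `truth.json` sidecar are written there.
#' @return A list:
#'   * `samples` — long repertoire tibble of all observed samples (already
#'     productive, frequencies **not** yet computed);
#'   * `truth` — per-patient list with the planted event labels and true
#'     frequency tables.
#' @export
generate_longitudinal_cohort <- function(config, n_patients = 1,
                                         biopsy = TRUE, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  biopsy <- rep_len(biopsy, n_patients)
  per_patient <- purrr::map(seq_len(n_patients), function(i) {
    seed_i <- as.integer(config$seed + 1000 * i)
    subject <- sprintf("SIM%03d", i)
    cfg_i <- config
    cfg_i$seed <- seed_i
    base <- generate_baseline(cfg_i)
    spiked <- spike_expansions(base, cfg_i, seed = seed_i + 1)

    samples <- list(observe_sample(
      spiked$baseline, config$depth,
      sample_id = paste0(subject, "_d", config$baseline_day),
      subject_id = subject, compartment = "blood",
      timepoint_days = config$baseline_day, seed = seed_i + 2
    ))
    for (k in seq_along(config$followup_days)) {
      day <- config$followup_days[k]
      fu_true <- spiked$followup
      fu_true$true_freq <- apply_drift(fu_true$true_freq,
        config$drift_sigma, seed = seed_i + 10 + 2 * k)
      samples[[length(samples) + 1]] <- observe_sample(
        fu_true, config$depth,
        sample_id = paste0(subject, "_d", day),
        subject_id = subject, compartment = "blood",
        timepoint_days = day, seed = seed_i + 11 + 2 * k
      )
    }
    if (biopsy[i]) {
      biopsy_true <- withr::with_seed(seed_i + 3, {
        donor <- spiked$baseline |> filter(.data$true_freq > 0)
        shared <- sample(nrow(donor),
          size = round(config$biopsy_shared_fraction * nrow(donor)))
        tibble(
          rearrangement = donor$rearrangement[shared],
          true_freq = donor$true_freq[shared] /
            sum(donor$true_freq[shared])
        )
      })
      samples[[length(samples) + 1]] <- observe_sample(
        biopsy_true, config$biopsy_depth,
        sample_id = paste0(subject, "_biopsy"),
        subject_id = subject, compartment = "tumor_biopsy",
        timepoint_days = config$baseline_day, seed = seed_i + 4
      )
    }
    list(
      subject_id = subject,
      samples = bind_rows(samples),
      truth = list(
        planted_new = spiked$truth$planted_new,
        planted_increased = spiked$truth$planted_increased,
        events = spiked$truth$events,
        true_baseline = spiked$baseline,
        true_followup = spiked$followup
      )
    )
  })

  samples <- bind_rows(purrr::map(per_patient, "samples"))
  truth <- setNames(purrr::map(per_patient, "truth"),
    purrr::map_chr(per_patient, "subject_id"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- purrr::map(per_patient, function(p) {
      files <- p$samples |>
        distinct(.data$sample_id, .data$compartment,
          .data$timepoint_days) |>
        mutate(file = paste0(.data$sample_id, ".tsv"))
      purrr::pwalk(files, function(sample_id, compartment, timepoint_days,
                                   file) {
        write_repertoire_tsv(
          filter(p$samples, .data$sample_id == !!sample_id),
          file.path(out_dir, file)
        )
      })
      list(subject_id = p$subject_id, samples = files)
    })
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA)
    truth_json <- purrr::map(truth, function(tr) {
      list(planted_new = tr$planted_new,
        planted_increased = tr$planted_increased,
        events = tr$events)
    })
    jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
      auto_unbox = TRUE, digits = NA)
  }

  list(samples = samples, truth = truth)
}

#' Simulate negative-control clone pairs
#'
#' Clone pairs from two draws of the same untreated repertoire, for
#' exercising the dispersion estimator and the comparator calibration: the
#' baseline draw is multinomial at `depth`; each clone's follow-up count is
#' drawn from a beta-binomial with the clone's true mean frequency and
#' intra-class overdispersion `rho` (`rho = 0` gives pure binomial
#' sampling, i.e. no biological drift).
#'
#' @param n_clones,depth Repertoire size and per-draw template count.
#' @param rho Overdispersion in \[0, 0.5).
#' @param seed Integer seed.
#' @param power_exponent Pareto tail index of the true clone-size law.
#' @return A clone-pair tibble as from [pair_samples()].
#' @export
simulate_control_pairs <- function(n_clones = 2000, depth = 2e5, rho = 0,
                                   seed = 1, power_exponent = 2) {
  if (rho < 0 || rho >= 0.5) {
    abort("`rho` must lie in [0, 0.5).", class = "clonotrack_value_error")
  }
  withr::with_seed(seed, {
    w <- runif(n_clones)^(-1 / power_exponent)
    p <- w / sum(w)
    x1 <- as.integer(rmultinom(1, depth, p))
    x2 <- if (rho == 0) {
      as.integer(rmultinom(1, depth, p))
    } else {
      sh <- bb_shapes(p, rho)
      p_draw <- stats::rbeta(n_clones, sh$alpha, sh$beta)
      as.integer(stats::rbinom(n_clones, depth, p_draw))
    }
    n1 <- sum(x1)
    n2 <- sum(x2)
    tibble(
      rearrangement = sprintf("CTRL%06d", seq_len(n_clones)),
      baseline_templates = x1,
      baseline_freq = x1 / n1,
      followup_templates = x2,
      followup_freq = x2 / n2,
      baseline_total = n1,
      followup_total = n2
    ) |>
      filter(.data$baseline_templates > 0 | .data$followup_templates > 0)
  })
}
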