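#' Configuration for the synthetic longitudinal ctDNA cohort
#'
#' Defaults emulate the monitoring-study design: 43 patients with 4--31
#' plasma samples each (mean ~8), outpatient visits every 56--84 days shared
#' between plasma draws and imaging, a 0.01% VAF detection floor, and about
#' half the patients with measurable ctDNA shedding. Tumor-fraction kinetics
#' follow exponential response decay with an emergent resistant clone per
#' therapy line; radiographic progression is declared when the tumor
#' fraction exceeds the nadir by a relative factor and an absolute floor.
#'
#' @param n_patients Number of patients.
#' @param samples_range Minimum and maximum samples per patient.
#' @param samples_nb_size,samples_nb_mu Negative-binomial parameters for the
#'   samples-per-patient count above the minimum (truncated at the maximum).
#' @param visit_interval_days Range of days between successive visits.
#' @param shedding_prevalence Fraction of patients with measurable shedding.
#' @param detection_floor VAF calling floor in percent.
#' @param tf_baseline_meanlog,tf_baseline_sdlog Log-normal parameters of the
#'   baseline tumor fraction in shedding patients.
#' @param k_resp Per-day exponential decay rate of the drug-sensitive tumor
#'   fraction under therapy.
#' @param k_grow Per-day exponential growth rate of the resistant clone.
#' @param resistance_min_days,resistance_mean_days Delay from therapy start
#'   to resistant-clone emergence: `resistance_min_days` plus an exponential
#'   tail with mean `resistance_mean_days`. The minimum reflects that
#'   acquired TKI resistance rarely emerges within the first months of an
#'   effective line.
#' @param tf_res0 Tumor fraction of the resistant clone at emergence.
#' @param pd_rel_factor,pd_abs_tf Radiographic progression is called at a
#'   visit when total tumor fraction >= max(pd_rel_factor * nadir, pd_abs_tf).
#' @param response_ratio A visit is "response" when total tumor fraction has
#'   fallen below this multiple of the previous visit's value.
#' @param therapy_change_prob Probability that radiographic progression
#'   triggers a therapy-line change.
#' @param intracranial_pd_prob Per-visit probability of intracranial-only
#'   progression in non-shedding patients.
#' @param n_trunk_variants_range,n_res_variants_range Ranges for the number
#'   of clonal (truncal) and resistant-clone variants.
#' @param germline_variants_per_patient,germline_vaf_mean,germline_vaf_sd
#'   Germline variants emitted in every sample, VAF ~ Normal clipped to
#'   \[30, 100\].
#' @param vaf_noise_sdlog Multiplicative log-normal noise on shed VAFs.
#' @param heterozygous_factor Tumor-fraction-to-VAF factor (0.5 for
#'   heterozygous variants in a diploid genome).
#' @param cn_altered_frac Fraction of autosomal genome carrying copy-number
#'   alteration in the per-patient segment profile.
#' @param segment_len_bins Range of copy-number segment lengths, in bins.
#' @param tmad_noise_sd Additive Gaussian noise per bin log2 ratio.
#' @param bin_width Bin width in bp.
#' @param autosome_bins Bins per autosome (3 autosomes in the desk-scale
#'   genome); a small X chromosome is included and excluded from t-MAD.
#' @param rng_seed Seed recorded in and applied by [simulate_cohort()].
#'
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 43,
                       samples_range = c(4, 31),
                       samples_nb_size = 2.2,
                       samples_nb_mu = 4.4,
                       visit_interval_days = c(56, 84),
                       shedding_prevalence = 0.63,
                       detection_floor = 0.01,
                       tf_baseline_meanlog = log(0.05),
                       tf_baseline_sdlog = 0.8,
                       k_resp = 0.035,
                       k_grow = 0.042,
                       resistance_min_days = 150,
                       resistance_mean_days = 100,
                       tf_res0 = 1e-4,
                       pd_rel_factor = 2,
                       pd_abs_tf = 0.06,
                       response_ratio = 0.7,
                       therapy_change_prob = 0.8,
                       intracranial_pd_prob = 0.03,
                       n_trunk_variants_range = c(2, 5),
                       n_res_variants_range = c(1, 2),
                       germline_variants_per_patient = 2,
                       germline_vaf_mean = 50,
                       germline_vaf_sd = 3,
                       vaf_noise_sdlog = 0.15,
                       heterozygous_factor = 0.5,
                       cn_altered_frac = 0.6,
                       segment_len_bins = c(10, 40),
                       tmad_noise_sd = 0.01,
                       bin_width = 1e6,
                       autosome_bins = 100,
                       rng_seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(k_resp = k_resp, k_grow = k_grow,
             tf_res0 = tf_res0, detection_floor = detection_floor,
             tmad_noise_sd = tmad_noise_sd, vaf_noise_sdlog = vaf_noise_sdlog)
  if (any(rates < 0)) stop("rates and noise scales must be >= 0", call. = FALSE)
  for (nm in c("samples_range", "visit_interval_days", "n_trunk_variants_range",
               "n_res_variants_range", "segment_len_bins")) {
    if (length(cfg[[nm]]) != 2 || cfg[[nm]][1] > cfg[[nm]][2]) {
      stop("`", nm, "` must be an ordered (min, max) pair", call. = FALSE)
    }
  }
  if (shedding_prevalence < 0 || shedding_prevalence > 1) {
    stop("shedding_prevalence must be in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# log2 ratio of a segment with `copies` copies at tumor fraction `tf`
cn_log2 <- function(copies, tf) {
  log2((2 * (1 - tf) + copies * tf) / 2)
}

sim_genome <- function(config) {
  tibble::tibble(
    chrom = c("chr1", "chr2", "chr3", "chrX"),
    length = c(rep(config$autosome_bins * config$bin_width, 3),
               20 * config$bin_width))
}

gene_pool <- function() {
  c("ALK", "TP53", "MET", "EGFR", "KRAS", "ERBB2", "PDGFRA", "KIT", "RET",
    "NRAS", "BRAF", "APC", "BRCA1")
}

agent_pool <- function() {
  c("crizotinib", "alectinib", "brigatinib", "lorlatinib", "chemotherapy")
}

draw_variants <- function(n, genome, class = "SNV") {
  auto <- genome[!is_sex_chrom(genome$chrom), ]
  idx <- sample.int(nrow(auto), n, replace = TRUE)
  tibble::tibble(
    chrom = auto$chrom[idx],
    pos = floor(stats::runif(n, 1, auto$length[idx])),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    gene = sample(gene_pool(), n, replace = TRUE),
    variant_class = class)
}

# The t-MAD median only tracks tumor fraction when more than half the
# retained genome deviates from neutral, so profiles are redrawn until the
# realized altered fraction reaches the configured level (deterministic
# given the RNG state).
draw_segments <- function(config, n_bins_autosomal) {
  for (attempt in 1:100) {
    states <- integer(0)
    while (length(states) < n_bins_autosomal) {
      len <- sample(config$segment_len_bins[1]:config$segment_len_bins[2], 1)
      altered <- stats::runif(1) < config$cn_altered_frac
      state <- if (altered) sample(c(1L, 3L, 4L), 1, prob = c(0.3, 0.5, 0.2)) else 2L
      states <- c(states, rep(state, len))
    }
    states <- states[seq_len(n_bins_autosomal)]
    if (mean(states != 2L) >= min(config$cn_altered_frac, 0.55)) return(states)
  }
  states
}

#' Simulate a synthetic longitudinal ctDNA cohort
#'
#' Generates, fully reproducibly from the configured seed: per-patient visit
#' schedules (plasma and imaging share dates), therapy lines with
#' exponential response decay and emergent resistant-clone growth, somatic
#' variant shedding with a detection floor, germline variants near 50% VAF,
#' per-sample genome-bin log2 copy-number profiles from a fixed per-patient
#' segment profile scaled by tumor fraction, RECIST-like status per visit,
#' and ground-truth molecular/radiographic progression days per therapy
#' line.
#'
#' @param config A [sim_config()].
#'
#' @return An object of class `ctdna_cohort`: list with tibbles `variants`
#'   (detected calls, VAF in percent), `bins` (long table of per-sample bin
#'   log2 ratios), `clinical` (per-sample annotations), `ground_truth` (per
#'   therapy line), `genome`, and the resolved `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  genome <- sim_genome(config)
  bins <- make_bin_template(genome, config$bin_width)$bins
  auto_bins <- !is_sex_chrom(bins$chrom)

  variants <- list(); bin_rows <- list(); clinical <- list(); truth <- list()

  for (p in seq_len(config$n_patients)) {
    patient_id <- sprintf("SYN_%02d", p)
    n_extra <- stats::rnbinom(1, size = config$samples_nb_size, mu = config$samples_nb_mu)
    n_samples <- min(config$samples_range[1] + n_extra, config$samples_range[2])
    gaps <- round(stats::runif(n_samples - 1, config$visit_interval_days[1],
                               config$visit_interval_days[2]))
    dates <- cumsum(c(0, gaps))
    shedder <- stats::runif(1) < config$shedding_prevalence

    seg_states <- draw_segments(config, sum(auto_bins))
    x_states <- rep(2L, sum(!auto_bins))
    germ <- draw_variants(config$germline_variants_per_patient, genome)

    trunk <- draw_variants(sample(
      config$n_trunk_variants_range[1]:config$n_trunk_variants_range[2], 1), genome)
    res_vars <- trunk[0, ]
    line_id <- 1L
    line_start <- 0
    tf_sens0 <- if (shedder) {
      stats::rlnorm(1, config$tf_baseline_meanlog, config$tf_baseline_sdlog)
    } else 0
    tf_sens0 <- min(tf_sens0, 0.5)
    t_res <- if (shedder) line_start + draw_resistance_delay(config) else Inf
    nadir <- Inf
    prev_tf <- NA_real_
    line_first_visit <- TRUE
    line_pd_day <- NA_real_
    line_t_res <- t_res
    line_visits <- numeric(0)

    # ground truth is recorded at sampling resolution: between-visit floor
    # crossings are unobservable by any assay run on the drawn samples
    flush_truth <- function(line_end_day) {
      emerged <- is.finite(line_t_res) && line_t_res <= line_end_day
      mol_day <- NA_real_
      if (emerged) {
        res_vaf <- ifelse(line_visits >= line_t_res,
                          100 * config$heterozygous_factor * config$tf_res0 *
                            exp(config$k_grow * (line_visits - line_t_res)), 0)
        hit <- which(res_vaf >= config$detection_floor)
        if (length(hit) > 0) mol_day <- line_visits[hit[1]]
      }
      truth[[length(truth) + 1]] <<- tibble::tibble(
        patient_id = patient_id, therapy_line_id = line_id,
        shedding = shedder,
        line_start_day = line_start, line_end_day = line_end_day,
        t_res_day = if (emerged) line_t_res else NA_real_,
        true_molecular_day = mol_day,
        true_radiographic_day = line_pd_day)
    }

    for (v in seq_len(n_samples)) {
      t <- dates[v]
      line_visits <- c(line_visits, t)
      sample_id <- sprintf("%s_S%02d", patient_id, v)
      if (t >= t_res && nrow(res_vars) == 0) {
        res_vars <- draw_variants(sample(
          config$n_res_variants_range[1]:config$n_res_variants_range[2], 1), genome)
      }
      tf_trunk <- tf_sens0 * exp(-config$k_resp * (t - line_start))
      tf_res <- if (t >= t_res) config$tf_res0 * exp(config$k_grow * (t - t_res)) else 0
      tf_tot <- min(tf_trunk + tf_res, 0.9)

      # RECIST-like status at this (shared imaging/plasma) visit
      if (line_first_visit) {
        status <- "baseline"
        nadir <- tf_tot
        line_first_visit <- FALSE
      } else {
        nadir <- min(nadir, tf_tot)
        pd_now <- shedder && tf_tot >= max(config$pd_rel_factor * nadir, config$pd_abs_tf)
        if (pd_now) {
          status <- if (stats::runif(1) < config$therapy_change_prob)
            "PD_therapy_change" else "PD"
        } else if (!shedder && stats::runif(1) < config$intracranial_pd_prob) {
          status <- "PD_intracranial"
        } else if (!is.na(prev_tf) && prev_tf > 0 &&
                   tf_tot <= config$response_ratio * prev_tf) {
          status <- "response"
        } else {
          status <- "stable"
        }
        if (status %in% pd_statuses() && is.na(line_pd_day)) line_pd_day <- t
      }
      prev_tf <- tf_tot

      clinical[[length(clinical) + 1]] <- tibble::tibble(
        patient_id = patient_id, sample_id = sample_id,
        sample_date_days = t, therapy_line_id = line_id,
        therapy_agent = agent_pool()[(line_id - 1) %% length(agent_pool()) + 1],
        recist_status = status, imaging_date_days = t)

      # somatic shedding: truncal variants ride the whole tumor fraction,
      # resistant-clone variants only its own component
      som <- dplyr::bind_rows(
        dplyr::mutate(trunk, carry = tf_tot),
        dplyr::mutate(res_vars, carry = tf_res))
      if (nrow(som) > 0 && tf_tot > 0) {
        vaf <- 100 * config$heterozygous_factor * som$carry *
          stats::rlnorm(nrow(som), 0, config$vaf_noise_sdlog)
        vaf <- pmin(vaf, 100)
        det <- vaf >= config$detection_floor
        if (any(det)) {
          variants[[length(variants) + 1]] <- tibble::tibble(
            sample_id = sample_id, patient_id = patient_id,
            chrom = som$chrom[det], pos = som$pos[det],
            ref = som$ref[det], alt = som$alt[det], gene = som$gene[det],
            variant_class = som$variant_class[det],
            vaf_percent = vaf[det])
        }
      }
      gvaf <- pmin(pmax(stats::rnorm(nrow(germ), config$germline_vaf_mean,
                                     config$germline_vaf_sd), 30), 100)
      variants[[length(variants) + 1]] <- tibble::tibble(
        sample_id = sample_id, patient_id = patient_id,
        chrom = germ$chrom, pos = germ$pos, ref = germ$ref, alt = germ$alt,
        gene = germ$gene, variant_class = germ$variant_class,
        vaf_percent = gvaf)

      # bin log2 profile: per-patient segment profile scaled by tumor fraction
      log2r <- c(cn_log2(seg_states, tf_tot), cn_log2(x_states, tf_tot)) +
        stats::rnorm(nrow(bins), 0, config$tmad_noise_sd)
      bin_rows[[length(bin_rows) + 1]] <- tibble::tibble(
        sample_id = sample_id, chrom = bins$chrom, start = bins$start,
        end = bins$end, log2r = log2r)

      # therapy switch the day after progression with therapy change
      if (status == "PD_therapy_change") {
        flush_truth(t)
        trunk <- dplyr::bind_rows(trunk, res_vars)
        res_vars <- trunk[0, ]
        line_id <- line_id + 1L
        line_start <- t + 1
        tf_sens0 <- tf_tot
        t_res <- line_start + draw_resistance_delay(config)
        line_t_res <- t_res
        nadir <- Inf
        line_first_visit <- TRUE
        line_pd_day <- NA_real_
        prev_tf <- NA_real_
        line_visits <- numeric(0)
      }
    }
    flush_truth(dates[n_samples])
  }

  structure(list(
    variants = dplyr::bind_rows(variants),
    bins = dplyr::bind_rows(bin_rows),
    clinical = dplyr::bind_rows(clinical),
    ground_truth = dplyr::bind_rows(truth),
    genome = genome,
    config = config), class = "ctdna_cohort")
}

draw_resistance_delay <- function(config) {
  config$resistance_min_days + stats::rexp(1, 1 / config$resistance_mean_days)
}

#' @export
print.ctdna_cohort <- function(x, ...) {
  cat(sprintf(
    "<ctdna_cohort> %d patients, %d samples, %d variant calls, %d therapy lines (seed %d)\n",
    dplyr::n_distinct(x$clinical$patient_id), nrow(x$clinical),
    nrow(x$variants), nrow(x$ground_truth), x$config$rng_seed))
  invisible(x)
}

#' Compute per-sample t-MAD scores for a synthetic cohort
#'
#' Routes each sample's bin log2 profile through [compute_tmad()].
#'
#' @param cohort A `ctdna_cohort`.
#'
#' @return A tibble: `sample_id`, `tmad`, `n_bins_used`.
#' @export
cohort_tmad <- function(cohort) {
  stopifnot(inherits(cohort, "ctdna_cohort"))
  dplyr::bind_rows(lapply(split(cohort$bins, cohort$bins$sample_id), function(df) {
    prof <- new_bin_profile(df[, c("chrom", "start", "end")], df$log2r,
                            "log2r", sample_id = df$sample_id[1])
    compute_tmad(prof)
  }))
}

#' Compare validated progression calls with simulator ground truth
#'
#' For every planted resistance event whose shed VAF crosses the detection
#' floor at a sampling point before radiographic progression in the same
#' therapy line, checks whether the pipeline produced a validated call in
#' that line whose lead time lies within one plasma-sampling interval (the
#' line's largest visit gap) of the ground-truth lead time.
#'
#' @param cohort A `ctdna_cohort`.
#' @param calls Validated calls from [validate_sustained()].
#'
#' @return A list with `events` (tibble, one row per eligible event:
#'   `recovered`, `best_call_date`, `true_molecular_day`,
#'   `timing_error_days`, `within_one_interval`) and `recovery_rate`
#'   (percent of eligible events with a timing-matched validated call).
#' @export
evaluate_recovery <- function(cohort, calls) {
  stopifnot(inherits(cohort, "ctdna_cohort"))
  gt <- cohort$ground_truth
  eligible <- gt[!is.na(gt$true_molecular_day) & !is.na(gt$true_radiographic_day) &
                   gt$true_molecular_day < gt$true_radiographic_day, , drop = FALSE]
  valid <- calls[which(calls$validated), , drop = FALSE]
  gaps <- dplyr::summarise(
    dplyr::group_by(cohort$clinical, .data$patient_id, .data$therapy_line_id),
    max_gap = if (dplyr::n() > 1) max(diff(sort(.data$sample_date_days))) else NA_real_,
    .groups = "drop")
  eligible <- dplyr::left_join(eligible, gaps,
                               by = c("patient_id", "therapy_line_id"))
  rows <- lapply(seq_len(nrow(eligible)), function(i) {
    ev <- eligible[i, ]
    cand <- valid[valid$patient_id == ev$patient_id &
                    valid$therapy_line_id == ev$therapy_line_id, , drop = FALSE]
    true_lead <- ev$true_radiographic_day - ev$true_molecular_day
    if (nrow(cand) == 0) {
      err <- NA_real_; best <- NA_real_
    } else {
      errs <- (ev$true_radiographic_day - cand$candidate_sample_date) - true_lead
      j <- which.min(abs(errs))
      err <- errs[j]; best <- cand$candidate_sample_date[j]
    }
    tibble::tibble(
      patient_id = ev$patient_id, therapy_line_id = ev$therapy_line_id,
      true_molecular_day = ev$true_molecular_day,
      true_radiographic_day = ev$true_radiographic_day,
      true_lead_time_days = true_lead,
      best_call_date = best, timing_error_days = err,
      interval_days = ev$max_gap,
      recovered = !is.na(best),
      within_one_interval = !is.na(err) && abs(err) <= ev$max_gap)
  })
  events <- dplyr::bind_rows(rows)
  list(events = events,
       recovery_rate = if (nrow(events) > 0)
         100 * mean(events$within_one_interval) else NA_real_)
}
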