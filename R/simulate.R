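#' Parameters for the synthetic source/sink transmission study
#'
#' Defines a study-shaped simulation: three subjects each maintaining a
#' fermented rice-bran bed (the source) whose community is conservative and
#' dominated by one lactic-acid-bacterium ASV, plus a subject-specific skin
#' (sink) community. Daily stirring during the contact phase transfers a
#' fraction of the source community onto the skin; after contact stops the
#' transferred fraction decays exponentially (shedding). Reads are drawn
#' multinomially at realistic depths.
#'
#' Defaults mirror the study conditions: dominant-ASV mass drawn uniformly
#' in \[0.69, 0.79\] per subject, sequencing depths uniform over
#' \[13053, 41949\] reads, Nukadoko sampling days \{0, 3, 6, 9, 12, 14\} and
#' skin timepoints \{0, 0', 3, ..., 14, 15, 18, ..., 29\}, with the skin
#' swab taken 6 h (0.25 d) after the day's stir.
#'
#' @param n_subjects Number of subjects (default 3).
#' @param n_source_asvs Source (bed) ASVs per subject (default 60).
#' @param n_sink_asvs Sink (skin) ASVs per subject (default 80).
#' @param dominant_mass Relative abundance of the dominant source ASV; a
#'   single number fixes it, `NULL` (default) draws one value per subject
#'   uniformly in `dominant_mass_range`.
#' @param dominant_mass_range Range for the per-subject draw.
#' @param source_noise_concentration Dirichlet concentration scaling for
#'   day-to-day wobble of the source community; larger is more conservative
#'   (default 2000). `Inf` freezes the community exactly.
#' @param transfer_fraction Fraction `f` of the skin community replaced by
#'   source material at each stir (default 0.10).
#' @param shedding_half_life Half-life of the transferred fraction, in days
#'   (default 0.5).
#' @param contact_lag_days Stir-to-swab gap absorbed as one shedding step
#'   before each contact-phase sample (default 0.25 d = 6 h).
#' @param depth_range Sequencing depth range, reads (uniform draw).
#' @param nukadoko_days Source sampling days.
#' @param skin_timepoints Sink timepoint labels; `"0"` is pre-interaction,
#'   `"0'"` is 6 h post-interaction on day 0.
#' @param threshold Shared-ASV threshold used when recording expected
#'   proportions in the ground truth (default 0.01).
#' @param overlap_abundance Off by default (0). When positive, one
#'   designated source ASV is also present in every sink baseline at this
#'   abundance (both sides), modelling ambient background sharing that is
#'   detectable even before any contact.
#' @param master_seed Integer master seed; all randomness derives from it.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_subjects = 3L,
                              n_source_asvs = 60L,
                              n_sink_asvs = 80L,
                              dominant_mass = NULL,
                              dominant_mass_range = c(0.69, 0.79),
                              source_noise_concentration = 2000,
                              transfer_fraction = 0.10,
                              shedding_half_life = 0.5,
                              contact_lag_days = 0.25,
                              depth_range = c(13053L, 41949L),
                              nukadoko_days = c(0L, 3L, 6L, 9L, 12L, 14L),
                              skin_timepoints = c("0", "0'", "3", "6", "9", "12",
                                                  "14", "15", "18", "21", "24",
                                                  "27", "29"),
                              threshold = 0.01,
                              overlap_abundance = 0,
                              master_seed = 1L) {
  if (!is_count(n_subjects) || n_subjects < 1) fmt_stop("n_subjects must be >= 1")
  if (!is_count(n_source_asvs) || n_source_asvs < 2) fmt_stop("n_source_asvs must be >= 2")
  if (!is_count(n_sink_asvs) || n_sink_asvs < 1) fmt_stop("n_sink_asvs must be >= 1")
  if (!is.null(dominant_mass) &&
      (dominant_mass <= 0 || dominant_mass >= 1)) {
    fmt_stop("dominant_mass must lie in (0, 1)")
  }
  if (transfer_fraction < 0 || transfer_fraction >= 1) {
    fmt_stop("transfer_fraction must lie in [0, 1)")
  }
  if (shedding_half_life <= 0) fmt_stop("shedding_half_life must be positive")
  if (source_noise_concentration <= 0) fmt_stop("source_noise_concentration must be positive")
  if (contact_lag_days < 0) fmt_stop("contact_lag_days must be >= 0")
  if (length(depth_range) != 2L || any(depth_range < 1) ||
      depth_range[[2L]] < depth_range[[1L]]) {
    fmt_stop("depth_range must be an increasing pair of positive depths")
  }
  if (overlap_abundance < 0 || overlap_abundance >= 0.5) {
    fmt_stop("overlap_abundance must lie in [0, 0.5)")
  }
  if (threshold < 0 || threshold >= 1) fmt_stop("threshold must lie in [0, 1)")
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_source_asvs = as.integer(n_source_asvs),
      n_sink_asvs = as.integer(n_sink_asvs),
      dominant_mass = dominant_mass,
      dominant_mass_range = dominant_mass_range,
      source_noise_concentration = source_noise_concentration,
      transfer_fraction = transfer_fraction,
      shedding_half_life = shedding_half_life,
      contact_lag_days = contact_lag_days,
      depth_range = as.integer(depth_range),
      nukadoko_days = as.integer(nukadoko_days),
      skin_timepoints = as.character(skin_timepoints),
      threshold = threshold,
      overlap_abundance = overlap_abundance,
      master_seed = as.integer(master_seed)
    ),
    class = "simulation_params"
  )
}

source_ids <- function(subject, n) sprintf("sub%s_src%03d", subject, seq_len(n))
sink_ids <- function(subject, n) sprintf("sub%s_snk%03d", subject, seq_len(n))

# stable integer key for a subject label, for seed derivation
subject_key <- function(subject) {
  sum(utf8ToInt(as.character(subject)) * seq_along(utf8ToInt(as.character(subject))))
}

# base (day-0) source community profile for one subject
source_base_profile <- function(params, subject, dominant_mass) {
  ids <- source_ids(subject, params$n_source_asvs)
  oa <- params$overlap_abundance
  rest_mass <- 1 - dominant_mass - oa
  if (rest_mass <= 0) fmt_stop("dominant_mass + overlap_abundance must be < 1")
  n_rest <- params$n_source_asvs - 1L - (oa > 0)
  rest <- rdirichlet1(rep(1, n_rest)) * rest_mass
  p <- c(dominant_mass, if (oa > 0) oa, rest)
  names(p) <- ids
  p
}

#' Simulate the source (rice-bran bed) time series for one subject
#'
#' One dominant ASV carries `dominant_mass` of the community; the remainder
#' is split by a flat Dirichlet draw. Each sampling day's profile is a
#' Dirichlet perturbation of the base profile with concentration
#' `source_noise_concentration` (larger = more conservative; `Inf` freezes
#' it). Counts are multinomial at a depth drawn from `depth_range`.
#'
#' @param params A [simulation_params()].
#' @param subject Subject label.
#' @param seed Optional integer seed (default derives from the master seed).
#' @return List: `profiles` (features x days matrix of true relative
#'   abundances), `counts` ([feature_table()]), `depths`, `dominant_id`,
#'   `dominant_mass`.
#' @export
simulate_source_series <- function(params, subject, seed = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  if (is.null(seed)) seed <- derive_seed(params$master_seed, 101L, subject_key(subject))
  with_seed(seed, {
    dm <- params$dominant_mass %||%
      stats::runif(1L, params$dominant_mass_range[[1L]], params$dominant_mass_range[[2L]])
    base <- source_base_profile(params, subject, dm)
    days <- params$nukadoko_days
    profiles <- vapply(days, function(d) {
      if (is.infinite(params$source_noise_concentration)) {
        base
      } else {
        p <- rdirichlet1(base * params$source_noise_concentration)
        names(p) <- names(base)
        p
      }
    }, numeric(length(base)))
    colnames(profiles) <- sprintf("nuka%s_d%02d", subject, days)
    depths <- round(stats::runif(length(days), params$depth_range[[1L]],
                                 params$depth_range[[2L]]))
    counts <- vapply(seq_along(days), function(j) {
      as.numeric(stats::rmultinom(1L, depths[[j]], profiles[, j]))
    }, numeric(nrow(profiles)))
    dimnames(counts) <- dimnames(profiles)
    list(
      profiles = profiles,
      counts = feature_table(counts),
      depths = depths,
      dominant_id = names(base)[[1L]],
      dominant_mass = dm
    )
  })
}

#' Simulate a subject-specific skin baseline community
#'
#' A sparse Dirichlet draw over the subject's sink ASVs, so communities
#' differ between subjects in both membership weight and evenness. By
#' default the sink universe is disjoint from every source universe, making
#' every shared detection attributable to transfer; with
#' `overlap_abundance > 0` the designated ambient source ASV is included at
#' that abundance.
#'
#' @param params A [simulation_params()].
#' @param subject Subject label.
#' @param seed Optional integer seed.
#' @return Named relative-abundance vector (the baseline profile).
#' @export
simulate_sink_baseline <- function(params, subject, seed = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  if (is.null(seed)) seed <- derive_seed(params$master_seed, 202L, subject_key(subject))
  with_seed(seed, {
    ids <- sink_ids(subject, params$n_sink_asvs)
    p <- rdirichlet1(rep(0.3, params$n_sink_asvs))
    names(p) <- ids
    oa <- params$overlap_abundance
    if (oa > 0) {
      ambient <- source_ids(subject, 2L)[[2L]] # the designated ambient source ASV
      p <- c(setNames(oa, ambient), p * (1 - oa))
    }
    p
  })
}

#' Mix transferred source material into a sink profile
#'
#' The transfer model: after a stir, the skin community is
#' `(1 - f) * sink + f * source` over the union of the two feature
#' universes. The mixture sums to one whenever the inputs do.
#'
#' @param sink_profile Named relative-abundance vector.
#' @param source_profile Named relative-abundance vector.
#' @param f Transfer fraction in `[0, 1)`.
#' @return Named relative-abundance vector over the union universe.
#' @export
apply_transfer <- function(sink_profile, source_profile, f) {
  if (f < 0 || f >= 1) fmt_stop("transfer fraction must lie in [0, 1)")
  u <- union(names(sink_profile), names(source_profile))
  s1 <- setNames(numeric(length(u)), u)
  s2 <- s1
  s1[names(sink_profile)] <- sink_profile
  s2[names(source_profile)] <- source_profile
  (1 - f) * s1 + f * s2
}

#' Exponential shedding of the transferred fraction
#'
#' `f_t = f * 2^(-elapsed / half_life)`: transferred material decays with a
#' fixed half-life once deposited — the decay-only model of microbial loss
#' from skin that the paired-sampling design can observe.
#'
#' @param f Initial transfer fraction.
#' @param elapsed Days since transfer, >= 0.
#' @param half_life Half-life in days, > 0.
#' @return Effective transfer fraction at `elapsed` days.
#' @export
apply_shedding <- function(f, elapsed, half_life) {
  if (any(elapsed < 0)) fmt_stop("elapsed must be >= 0")
  if (half_life <= 0) fmt_stop("half_life must be positive")
  f * 2^(-elapsed / half_life)
}

skin_day <- function(timepoint) as.integer(sub("'", "", timepoint, fixed = TRUE))

#' Generate a complete study-shaped synthetic dataset with ground truth
#'
#' Produces a feature table, metadata, taxonomy and a `synthetic_truth`
#' object for the full design: per subject, a conservative source series
#' over the Nukadoko sampling days and a skin series over all timepoints.
#' The pre-interaction sample (`"0"`) is the pure baseline; every other
#' contact-phase sample mixes that day's source profile into the baseline
#' at `f * 2^(-contact_lag_days / half_life)` (the stir-to-swab gap is one
#' shedding step); no-contact samples decay the day-14 transfer as
#' `f * 2^(-(day - 14 + contact_lag_days) / half_life)`. All counts are
#' multinomial at depths drawn from `depth_range`; identical master seeds
#' give bit-identical datasets.
#'
#' The taxonomy assigns each subject's dominant source ASV the distinctive
#' genus `Loigolactibacillus`; the ambient overlap ASV (when enabled) is
#' `Unassigned`.
#'
#' @param params A [simulation_params()].
#' @return A `synthetic_study` list: `table` ([feature_table()]), `meta`
#'   ([sample_metadata()]), `tax` ([taxonomy_map()]), `truth`
#'   (`synthetic_truth`: per-timepoint expected profiles-derived shared
#'   proportions, transferred ids, effective transfer fractions, seeds).
#' @export
generate_study <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  subjects <- as.character(seq_len(params$n_subjects))
  f <- params$transfer_fraction
  h <- params$shedding_half_life
  lag <- params$contact_lag_days

  source_genera <- c("Pantoea", "Xanthomonas", "Staphylococcus",
                     "Lactiplantibacillus", "Leuconostoc", "Weissella",
                     "Pediococcus", "Enterobacter")
  sink_genera <- c("Cutibacterium", "Staphylococcus", "Pseudomonas",
                   "Acinetobacter", "Kocuria", "Corynebacterium",
                   "Micrococcus", "Streptococcus", "Moraxella")

  all_counts <- list()
  meta_rows <- list()
  tax_rows <- list()
  truth_rows <- list()
  transferred <- list()
  seeds_used <- list(master = params$master_seed)

  for (s_idx in seq_along(subjects)) {
    subject <- subjects[[s_idx]]
    src_seed <- derive_seed(params$master_seed, 101L, s_idx)
    snk_seed <- derive_seed(params$master_seed, 202L, s_idx)
    seeds_used[[paste0("source_", subject)]] <- src_seed
    seeds_used[[paste0("sink_", subject)]] <- snk_seed

    src <- simulate_source_series(params, subject, seed = src_seed)
    baseline <- simulate_sink_baseline(params, subject, seed = snk_seed)

    # source samples and metadata
    all_counts[[length(all_counts) + 1L]] <- unclass_matrix(src$counts)
    src_samples <- colnames(src$profiles)
    meta_rows[[length(meta_rows) + 1L]] <- data.frame(
      sample_id = src_samples, subject = subject, substrate = "nukadoko",
      day = params$nukadoko_days,
      timepoint = as.character(params$nukadoko_days),
      phase = ifelse(params$nukadoko_days <= 14L, "contact", "no_contact"),
      stringsAsFactors = FALSE
    )

    # taxonomy for this subject's features
    sids <- source_ids(subject, params$n_source_asvs)
    src_genus <- with_seed(derive_seed(params$master_seed, 303L, s_idx), {
      sample(source_genera, params$n_source_asvs, replace = TRUE)
    })
    src_tax <- sprintf(
      "d__Bacteria; p__SimPhylum; c__SimClass; o__SimOrder; f__SimFamily; g__%s",
      src_genus
    )
    src_tax[[1L]] <- paste(
      "d__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales;",
      "f__Lactobacillaceae; g__Loigolactibacillus"
    )
    if (params$overlap_abundance > 0) src_tax[[2L]] <- "Unassigned"
    kids <- sink_ids(subject, params$n_sink_asvs)
    snk_genus <- with_seed(derive_seed(params$master_seed, 404L, s_idx), {
      sample(sink_genera, params$n_sink_asvs, replace = TRUE)
    })
    snk_tax <- sprintf(
      "d__Bacteria; p__SkinPhylum; c__SkinClass; o__SkinOrder; f__SkinFamily; g__%s",
      snk_genus
    )
    tax_rows[[length(tax_rows) + 1L]] <- data.frame(
      feature_id = c(sids, kids), taxon = c(src_tax, snk_tax),
      stringsAsFactors = FALSE
    )

    transferred[[subject]] <- sids

    # skin expected profiles per timepoint
    day14_col <- which(params$nukadoko_days == 14L)
    skin_profiles <- list()
    for (tp in params$skin_timepoints) {
      day <- skin_day(tp)
      if (tp == "0") {
        prof <- apply_transfer(baseline, src$profiles[, 1L], 0) # pure baseline, union universe
        f_eff <- 0
        src_col <- 1L
      } else if (day <= 14L) {
        src_col <- which(params$nukadoko_days == day)
        if (!length(src_col)) {
          fmt_stop("no source sampling day matching contact skin day %d", day)
        }
        f_eff <- apply_shedding(f, lag, h)
        prof <- apply_transfer(baseline, src$profiles[, src_col], f_eff)
      } else {
        if (!length(day14_col)) fmt_stop("no day-14 source sample for shedding phase")
        src_col <- day14_col
        f_eff <- apply_shedding(f, (day - 14L) + lag, h)
        prof <- apply_transfer(baseline, src$profiles[, src_col], f_eff)
      }
      skin_profiles[[tp]] <- prof

      # ground-truth expected shared proportion at the recording threshold,
      # against the profile of the source sample the pairing rule selects
      pair_src_col <- if (day <= 14L) src_col else day14_col
      src_prof_full <- setNames(numeric(length(prof)), names(prof))
      src_prof_full[rownames(src$profiles)] <- src$profiles[, pair_src_col]
      shared <- names(prof)[src_prof_full > params$threshold & prof > params$threshold]
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        subject = subject, day = day, timepoint = tp,
        phase = ifelse(day <= 14L, "contact", "no_contact"),
        f_effective = f_eff,
        expected_shared_proportion = 100 * sum(prof[shared]),
        n_expected_shared = length(shared),
        stringsAsFactors = FALSE
      )
    }

    # skin counts
    skin_samples <- sprintf("skin%s_t%s", subject,
                            sub("'", "p", params$skin_timepoints, fixed = TRUE))
    skin_counts <- with_seed(derive_seed(params$master_seed, 505L, s_idx), {
      depths <- round(stats::runif(length(skin_profiles),
                                   params$depth_range[[1L]], params$depth_range[[2L]]))
      m <- vapply(seq_along(skin_profiles), function(j) {
        as.numeric(stats::rmultinom(1L, depths[[j]], skin_profiles[[j]]))
      }, numeric(length(skin_profiles[[1L]])))
      rownames(m) <- names(skin_profiles[[1L]])
      colnames(m) <- skin_samples
      m
    })
    all_counts[[length(all_counts) + 1L]] <- skin_counts
    skin_days <- skin_day(params$skin_timepoints)
    meta_rows[[length(meta_rows) + 1L]] <- data.frame(
      sample_id = skin_samples, subject = subject, substrate = "skin",
      day = skin_days, timepoint = params$skin_timepoints,
      phase = ifelse(skin_days <= 14L, "contact", "no_contact"),
      stringsAsFactors = FALSE
    )
  }

  # assemble the union feature universe
  all_features <- unique(unlist(lapply(all_counts, rownames)))
  mat <- matrix(0, nrow = length(all_features),
                ncol = sum(vapply(all_counts, ncol, integer(1L))),
                dimnames = list(all_features, unlist(lapply(all_counts, colnames))))
  for (blk in all_counts) {
    mat[rownames(blk), colnames(blk)] <- mat[rownames(blk), colnames(blk)] + blk
  }

  tax <- do.call(rbind, tax_rows)
  tax <- tax[!duplicated(tax$feature_id), , drop = FALSE]
  truth_df <- do.call(rbind, truth_rows)
  rownames(truth_df) <- NULL

  structure(
    list(
      table = feature_table(mat),
      meta = sample_metadata(do.call(rbind, meta_rows)),
      tax = taxonomy_map(tax),
      truth = structure(
        list(
          per_timepoint = truth_df,
          transferred = transferred,
          transfer_fraction = f,
          shedding_half_life = h,
          contact_lag_days = lag,
          threshold = params$threshold,
          dominant = lapply(setNames(subjects, subjects), function(s) {
            source_ids(s, 1L)
          }),
          seeds = seeds_used
        ),
        class = "synthetic_truth"
      )
    ),
    class = "synthetic_study"
  )
}

#' Write a synthetic study to disk as the standard artefacts
#'
#' Emits `feature_table.tsv`, `metadata.tsv`, `taxonomy.tsv` (the same
#' dialects the readers accept) and `truth.json` under `dir`.
#'
#' @param study A `synthetic_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    table = file.path(dir, "feature_table.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_feature_table(study$table, paths[["table"]])
  write_metadata(study$meta, paths[["metadata"]])
  write_taxonomy(study$tax, paths[["taxonomy"]])
  jsonlite::write_json(
    list(
      per_timepoint = study$truth$per_timepoint,
      transferred = study$truth$transferred,
      transfer_fraction = study$truth$transfer_fraction,
      shedding_half_life = study$truth$shedding_half_life,
      contact_lag_days = study$truth$contact_lag_days,
      threshold = study$truth$threshold,
      seeds = study$truth$seeds
    ),
    paths[["truth"]], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d features x %d samples, %d subject(s); f = %.3g, half-life %.3g d\n",
    nrow(x$table), ncol(x$table), length(unique(x$meta$subject)),
    x$truth$transfer_fraction, x$truth$shedding_half_life
  ))
  invisible(x)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> f = %.3g, half-life %.3g d, threshold %.3g; %d timepoint rows\n",
    x$transfer_fraction, x$shedding_half_life, x$threshold,
    nrow(x$per_timepoint)
  ))
  invisible(x)
}
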