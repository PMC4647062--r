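# Cohort assembly and the statistical battery: group summaries, t/ANOVA
# comparisons with Bonferroni correction and effect sizes, Pearson
# correlations, and the genotype-by-class direction summary.

.FEATURE_UNITS <- c(
  R_N_MOhm = "MOhm", sag_ratio = "ratio", rebound_slope = "mV/mV",
  tau_slow_ms = "ms", f_R_Hz = "Hz", summation_ratio = "ratio",
  V_rest_mV = "mV", threshold_short_mV = "mV", threshold_long_mV = "mV",
  current_short_pA = "pA", current_long_pA = "pA",
  I_K_total_peak_pA = "pA", I_KA_fast_peak_pA = "pA",
  I_K_slow_peak_pA = "pA", I_K_sustained_pA = "pA",
  frac_fast = "fraction", frac_slow = "fraction",
  frac_sustained = "fraction", I_h_max_pA = "pA")

#' Extract the full feature battery from one model cell
#'
#' Runs the standard protocols on a [neuron_spec()] and returns the per-cell
#' feature record used by the cohort pipeline: subthreshold properties from
#' the step family, chirp, brief pulses, EPSC train and bias-free sweep;
#' spike thresholds/just-threshold currents at a short and a long pulse
#' duration; and outside-out patch measurements (K+ component peaks and
#' fractions, maximal h-current) from a somatic patch with the cell's own
#' channel densities.
#'
#' @param neuron a [neuron_spec()].
#' @param features which blocks to run (`"subthreshold"`, `"spikes"`,
#'   `"vclamp"`).
#' @param threshold_durations_ms short/long just-threshold pulse durations.
#' @param step_amplitudes_pA step-family amplitudes; a hyperpolarizing-only
#'   subset still yields sag and rebound but no input resistance.
#' @param patch_noise_pA recording-noise SD for the simulated patch.
#' @param cc_noise_mV recording-noise SD for current-clamp sweeps (the
#'   experimental battery is not noise-free; features are extracted from
#'   realistically noisy traces).
#' @param patch_area_fraction patch membrane fraction.
#' @param seed seed for patch noise.
#' @return Named list of numeric features.
#' @export
extract_cell_features <- function(neuron,
                                  features = c("subthreshold", "spikes",
                                               "vclamp"),
                                  threshold_durations_ms = c(1.5, 100),
                                  step_amplitudes_pA = seq(-150, 50,
                                                           by = 20),
                                  patch_noise_pA = 2,
                                  cc_noise_mV = 0.2,
                                  patch_area_fraction = 0.05,
                                  seed = 1L) {
  out <- list()
  if ("subthreshold" %in% features) {
    steps <- run_step_family(neuron, amplitudes_pA = step_amplitudes_pA,
                             noise_mV_sd = cc_noise_mV, seed = seed * 17L)
    ch <- run_chirp(neuron, noise_mV_sd = cc_noise_mV, seed = seed * 17L + 101L)
    pulses <- run_brief_pulses(neuron, n_sweeps = 20, amplitude_pA = -300,
                               noise_mV_sd = cc_noise_mV,
                               seed = seed * 17L + 200L)
    train <- run_epsc_train(neuron, noise_mV_sd = cc_noise_mV,
                            seed = seed * 17L + 301L)
    rest <- run_rest(neuron, noise_mV_sd = cc_noise_mV,
                     seed = seed * 17L + 302L)
    sub <- suppressWarnings(
      extract_subthreshold(steps, ch, pulses, train, rest))
    out <- c(out, sub[c("R_N_MOhm", "sag_ratio", "rebound_slope",
                        "tau_slow_ms", "f_R_Hz", "summation_ratio",
                        "V_rest_mV")])
  }
  if ("spikes" %in% features) {
    stim <- make_threshold_stimulator(neuron)
    short <- just_threshold_search(stim, threshold_durations_ms[1],
                                   start_pA = 1500)
    long <- just_threshold_search(stim, threshold_durations_ms[2],
                                  start_pA = 300)
    out$threshold_short_mV <- short$features$threshold_mV
    out$threshold_long_mV <- long$features$threshold_mV
    out$current_short_pA <- short$amplitude_pA
    out$current_long_pA <- long$amplitude_pA
  }
  if ("vclamp" %in% features) {
    k_chans <- patch_channels_from(neuron, "soma",
                                   exclude = c("NaT", "K_DR", "H"))
    ih_chans <- patch_channels_from(neuron, "soma",
                                    include = c("leak", "H"))
    patch <- patch_spec(area_fraction = patch_area_fraction,
                        noise_pA_sd = patch_noise_pA, seed = seed)
    dec <- run_k_decomposition(k_chans, patch)
    ih <- run_ih_protocol(ih_chans, patch)
    out$I_K_total_peak_pA <- unname(dec$peaks_pA["total"])
    out$I_KA_fast_peak_pA <- unname(dec$peaks_pA["KA_fast"])
    out$I_K_slow_peak_pA <- unname(dec$peaks_pA["K_slow"])
    out$I_K_sustained_pA <- dec$sustained_pA
    out$frac_fast <- unname(dec$fractions["fast"])
    out$frac_slow <- unname(dec$fractions["slow"])
    out$frac_sustained <- unname(dec$fractions["sustained"])
    out$I_h_max_pA <- ih$I_h_max_pA
  }
  out
}

#' Build a feature table from simulated cohorts
#'
#' Samples each cohort with [sample_cohort()], runs
#' [extract_cell_features()] on every cell and assembles the tidy
#' per-cell-by-feature table.
#'
#' @param cohorts list of [cohort_spec()] objects.
#' @param features feature blocks, as in [extract_cell_features()].
#' @param drug optional drug name applied to every cell (see
#'   [apply_pharmacology()]).
#' @param ... further arguments to [extract_cell_features()].
#' @return A [feature_table()].
#' @export
cohort_feature_table <- function(cohorts, features = c("subthreshold",
                                                       "spikes", "vclamp"),
                                 drug = NULL, ...) {
  rows <- list()
  for (cs in cohorts) {
    cells <- sample_cohort(cs)
    for (i in seq_along(cells)) {
      cell <- cells[[i]]
      if (!is.null(drug)) cell <- apply_pharmacology(cell, drug)
      fv <- extract_cell_features(cell, features = features,
                                  seed = cs$seed * 1000L + i, ...)
      fv <- fv[!vapply(fv, function(v) is.null(v) || is.na(v), logical(1))]
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cell$preset_id, genotype = cs$genotype,
        projection_class = cs$projection_class, compartment = "soma",
        distance_um = 0, feature = names(fv),
        value = as.numeric(unlist(fv)),
        units = unname(.FEATURE_UNITS[names(fv)]),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  feature_table(df$cell_id, df$genotype, df$projection_class,
                df$compartment, df$distance_um, df$feature, df$value,
                df$units)
}

#' Group comparison design
#'
#' @param factors metadata columns defining the groups (subset of
#'   `genotype`, `projection_class`, `compartment`).
#' @param design `"between"` (independent groups) or `"repeated"` (paired by
#'   cell).
#' @param alpha significance level.
#' @param correction `"bonferroni"` or `"none"`.
#' @param family_size number of comparisons in the declared family (used by
#'   the Bonferroni correction).
#' @return An object of class `"group_design"`.
#' @export
group_design <- function(factors = "genotype",
                         design = c("between", "repeated"), alpha = 0.05,
                         correction = c("bonferroni", "none"),
                         family_size = 1L) {
  design <- match.arg(design)
  correction <- match.arg(correction)
  ok <- factors %in% c("genotype", "projection_class", "compartment")
  if (!all(ok)) stop("unknown design factor(s): ",
                     paste(factors[!ok], collapse = ", "), call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  structure(list(factors = factors, design = design, alpha = alpha,
                 correction = correction,
                 family_size = as.integer(family_size)),
            class = "group_design")
}

.table_feature <- function(table, feature, subset = NULL) {
  df <- table[table$feature == feature, , drop = FALSE]
  if (!is.null(subset)) {
    for (nm in names(subset)) df <- df[df[[nm]] %in% subset[[nm]], ,
                                       drop = FALSE]
  }
  if (!nrow(df)) stop("no rows for feature '", feature, "'", call. = FALSE)
  df
}

#' Group means with SEM
#'
#' @param table a [feature_table()].
#' @param design a [group_design()].
#' @param feature feature to summarize (all features when `NULL`).
#' @param subset optional named list of metadata filters.
#' @return `data.frame` with the group columns, `feature`, `mean`, `sem`,
#'   `n`.
#' @export
summarize_groups <- function(table, design = group_design(),
                             feature = NULL, subset = NULL) {
  feats <- if (is.null(feature)) unique(table$feature) else feature
  out <- lapply(feats, function(f) {
    df <- .table_feature(table, f, subset)
    grp <- interaction(df[design$factors], drop = TRUE, sep = ":")
    agg <- do.call(rbind, lapply(split(df$value, grp), function(v)
      data.frame(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
                 n = length(v))))
    if (any(agg$n < 2))
      stop("group(s) with n < 2 for feature '", f, "'", call. = FALSE)
    data.frame(group = rownames(agg), feature = f, agg, row.names = NULL)
  })
  do.call(rbind, out)
}

.cohens_d <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * stats::var(x) +
                (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  if (sp == 0) return(0)
  abs(mean(x) - mean(y)) / sp
}

#' Compare groups for one feature
#'
#' Two groups: Student's t test (paired when the design is repeated and the
#' cells match); more: ANOVA over the design factors. Each group is screened
#' for normality with a Kolmogorov-Smirnov test, the p value is
#' Bonferroni-adjusted across the declared comparison family, and the effect
#' size is Cohen's d (pooled SD, two groups) or Cohen's f (from the ANOVA
#' sums of squares).
#'
#' @param table a [feature_table()].
#' @param feature feature name.
#' @param design a [group_design()].
#' @param subset optional named list of metadata filters (e.g.
#'   `list(projection_class = "PT")`).
#' @return An object of class `"comparison_result"`: list with the group
#'   summary, `statistic`, `p_value`, `p_adjusted`, `effect_size`,
#'   `normality_p`, `significant`.
#' @export
compare_groups <- function(table, feature, design = group_design(),
                           subset = NULL) {
  df <- .table_feature(table, feature, subset)
  grp <- interaction(df[design$factors], drop = TRUE, sep = ":")
  groups <- split(df$value, grp)
  if (length(groups) < 2L) stop("need >= 2 groups to compare",
                                call. = FALSE)
  norm_p <- vapply(groups, function(v) {
    if (length(v) < 3 || stats::sd(v) == 0) return(NA_real_)
    suppressWarnings(stats::ks.test((v - mean(v)) / stats::sd(v),
                                    "pnorm")$p.value)
  }, numeric(1))
  if (length(groups) == 2L) {
    x <- groups[[1]]; y <- groups[[2]]
    if (stats::sd(c(x, y)) == 0) {
      stat <- 0; p <- 1
    } else if (design$design == "repeated" && length(x) == length(y)) {
      tt <- stats::t.test(x, y, paired = TRUE)
      stat <- unname(tt$statistic); p <- tt$p.value
    } else {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      stat <- unname(tt$statistic); p <- tt$p.value
    }
    eff <- .cohens_d(x, y)
  } else {
    fml <- stats::as.formula(paste("value ~",
                                   paste(design$factors, collapse = "*")))
    fit <- stats::aov(fml, data = df)
    tab <- summary(fit)[[1]]
    stat <- tab$`F value`[1]
    p <- tab$`Pr(>F)`[1]
    ss <- tab$`Sum Sq`
    eta2 <- sum(ss[-length(ss)]) / sum(ss)
    eff <- sqrt(eta2 / max(1 - eta2, 1e-12))
  }
  p_adj <- if (design$correction == "bonferroni")
    min(1, p * design$family_size) else p
  means <- vapply(groups, mean, numeric(1))
  structure(list(
    feature = feature, groups = names(groups), means = means,
    sems = vapply(groups, function(v) stats::sd(v) / sqrt(length(v)),
                  numeric(1)),
    n = vapply(groups, length, numeric(1)),
    statistic = stat, p_value = p, p_adjusted = p_adj,
    effect_size = eff, normality_p = norm_p,
    significant = p_adj < design$alpha),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison> %s: %s\n", x$feature,
              paste(sprintf("%s %.3g+/-%.2g (n=%d)", x$groups, x$means,
                            x$sems, x$n), collapse = " vs ")))
  cat(sprintf("  stat %.3g, p %.3g (adj %.3g), effect %.3g%s\n", x$statistic,
              x$p_value, x$p_adjusted, x$effect_size,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Pearson correlation between two features
#'
#' @param table a [feature_table()].
#' @param x_feature,y_feature feature names, paired by cell.
#' @param subset optional metadata filter.
#' @return List with `r_squared`, `r`, `p_value`, `n`.
#' @export
correlate <- function(table, x_feature, y_feature, subset = NULL) {
  dx <- .table_feature(table, x_feature, subset)
  dy <- .table_feature(table, y_feature, subset)
  common <- intersect(dx$cell_id, dy$cell_id)
  if (length(common) < 4L)
    stop("correlate needs >= 4 paired observations", call. = FALSE)
  x <- dx$value[match(common, dx$cell_id)]
  y <- dy$value[match(common, dy$cell_id)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the features", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r_squared = unname(ct$estimate)^2, r = unname(ct$estimate),
       p_value = ct$p.value, n = length(common))
}

#' Genotype direction summary across features and cell classes
#'
#' Maps each knockout-vs-wild-type comparison to `"up"`, `"down"` or
#' `"unchanged"`: unchanged when the adjusted p value is not below alpha,
#' otherwise the sign of (KO mean - WT mean).
#'
#' @param comparisons named list of `"comparison_result"` objects whose two
#'   groups are the WT and KO cohorts (group labels must contain "WT"/"KO");
#'   names carry `feature` and optionally class.
#' @param alpha significance level.
#' @return `data.frame` with `comparison`, `feature`, `direction`.
#' @export
direction_summary <- function(comparisons, alpha = 0.05) {
  rows <- lapply(seq_along(comparisons), function(i) {
    cm <- comparisons[[i]]
    iko <- grep("KO", cm$groups)
    iwt <- grep("WT", cm$groups)
    if (length(iko) != 1L || length(iwt) != 1L)
      stop("comparison ", i, " is not a WT-vs-KO two-group comparison",
           call. = FALSE)
    dir <- if (cm$p_adjusted >= alpha) "unchanged"
           else if (cm$means[iko] > cm$means[iwt]) "up" else "down"
    data.frame(comparison = if (is.null(names(comparisons)[i]) ||
                                is.na(names(comparisons)[i]))
                              as.character(i) else names(comparisons)[i],
               feature = cm$feature, direction = dir,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' End-to-end cohort pipeline
#'
#' Simulates the four genotype-by-class cohorts, extracts features, runs the
#' per-class knockout-vs-wild-type comparison battery and builds the
#' direction summary. Fully seeded: the same configuration yields identical
#' output.
#'
#' @param config list with elements `n_cells` (per cohort), `seed`,
#'   `features` (blocks for [extract_cell_features()]), `alpha`,
#'   `family_size` (Bonferroni family; defaults to the number of features
#'   compared per class), and optionally `classes` (default `c("PT","IT")`)
#'   and `drug`.
#' @return List with `feature_table`, `comparisons` (named list),
#'   `directions` (`data.frame`), and `config`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(n_cells = 15L, seed = 1L,
                                features = c("subthreshold", "spikes",
                                             "vclamp"),
                                alpha = 0.05, family_size = NULL,
                                classes = c("PT", "IT"), drug = NULL),
                           config)
  bad <- setdiff(cfg$features, c("subthreshold", "spikes", "vclamp"))
  if (length(bad))
    stop("unknown feature block(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cohorts <- list()
  for (cl in cfg$classes) {
    for (gt in c("WT", "KO")) {
      cohorts[[paste(gt, cl, sep = "-")]] <-
        cohort_spec(gt, cl, n_cells = cfg$n_cells,
                    seed = cfg$seed + length(cohorts))
    }
  }
  tab <- cohort_feature_table(cohorts, features = cfg$features,
                              drug = cfg$drug)
  feats <- unique(tab$feature)
  fam <- if (is.null(cfg$family_size)) length(feats) else cfg$family_size
  des <- group_design("genotype", alpha = cfg$alpha,
                      family_size = fam)
  comparisons <- list()
  for (cl in cfg$classes) {
    for (f in feats) {
      comparisons[[paste(cl, f, sep = ".")]] <-
        compare_groups(tab, f, des, subset = list(projection_class = cl))
    }
  }
  list(feature_table = tab, comparisons = comparisons,
       directions = direction_summary(comparisons, cfg$alpha),
       config = cfg)
}
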