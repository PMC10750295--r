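# Synthetic-data generators with planted ground truth. Every generator is a
# pure function of (config, seed): it routes all randomness through an
# explicit seed without touching the caller's RNG, and emits a truth table
# sufficient to score recovery without re-deriving the plant.

#' Configuration for a synthetic drug-response screen
#'
#' Defaults emulate the screened breast-cancer panel: ~58 lines over three
#' subtypes (Luminal, Basal, HER2) and a library of drugs scored as IC50
#' z-scores.
#'
#' @param n_lines_per_subtype named integer vector, subtype -> line count.
#' @param n_drugs number of drugs (>= number of planted drugs).
#' @param planted data.frame with columns `drug_id`, `subtype`, `shift`
#'   (z units; negative = more sensitive) or NULL for a null screen.
#' @param noise_sd positive residual sd on the z scale (default 1: the
#'   z-scores are standardized over the whole panel, so unit noise is the
#'   null-world scale).
#' @return list of class `ScreenSimConfig`.
#' @export
screen_sim_config <- function(n_lines_per_subtype = c(Luminal = 25, Basal = 22, HER2 = 11),
                              n_drugs = 100L, planted = NULL, noise_sd = 1) {
  if (length(n_lines_per_subtype) < 2L) stop_sx("need >= 2 subtypes")
  if (is.null(names(n_lines_per_subtype))) stop_sx("subtype counts must be named")
  if (any(n_lines_per_subtype < 1L)) stop_sx("subtype counts must be positive")
  if (noise_sd <= 0) stop_sx("noise_sd must be positive")
  if (!is.null(planted)) {
    need <- c("drug_id", "subtype", "shift")
    if (!all(need %in% colnames(planted))) {
      stop_sx("planted needs columns: ", paste(need, collapse = ", "))
    }
    if (!all(planted$subtype %in% names(n_lines_per_subtype))) {
      stop_sx("planted effect references unknown subtype")
    }
    if (n_drugs < length(unique(planted$drug_id))) {
      stop_sx("n_drugs smaller than number of planted drugs")
    }
  }
  structure(list(n_lines_per_subtype = n_lines_per_subtype,
                 n_drugs = as.integer(n_drugs), planted = planted,
                 noise_sd = noise_sd),
            class = "ScreenSimConfig")
}

#' Simulate a subtype-structured drug-response screen
#'
#' Unplanted cells draw from Normal(0, noise_sd); a planted (drug, subtype)
#' effect shifts that subtype's cells to Normal(shift, noise_sd). Negative
#' shifts mean lower IC50 z, i.e. greater sensitivity.
#'
#' @param cfg a [screen_sim_config()].
#' @param seed integer seed.
#' @return list with `response` ([drug_response_matrix()]), `annotation`
#'   ([sample_annotation()]) and `truth` (data.frame of planted effects).
#' @export
simulate_drug_response <- function(cfg, seed) {
  stopifnot(inherits(cfg, "ScreenSimConfig"))
  with_seed(seed, {
    subtypes <- names(cfg$n_lines_per_subtype)
    subtype_per_line <- rep(subtypes, cfg$n_lines_per_subtype)
    n_lines <- length(subtype_per_line)
    line_ids <- sprintf("line%03d", seq_len(n_lines))
    drug_ids <- sprintf("drug%03d", seq_len(cfg$n_drugs))
    z <- matrix(stats::rnorm(n_lines * cfg$n_drugs, 0, cfg$noise_sd),
                n_lines, cfg$n_drugs, dimnames = list(line_ids, drug_ids))
    truth <- data.frame(drug_id = character(0), subtype = character(0),
                        shift = numeric(0), stringsAsFactors = FALSE)
    if (!is.null(cfg$planted) && nrow(cfg$planted) > 0L) {
      planted <- cfg$planted
      # planted drug_ids may name drugs directly or be assigned to the first columns
      planted$drug_id <- as.character(planted$drug_id)
      unknown <- !planted$drug_id %in% drug_ids
      if (any(unknown)) {
        planted$drug_id[unknown] <- drug_ids[seq_len(sum(unknown))]
      }
      for (i in seq_len(nrow(planted))) {
        rows <- subtype_per_line == planted$subtype[[i]]
        z[rows, planted$drug_id[[i]]] <- z[rows, planted$drug_id[[i]]] +
          planted$shift[[i]]
      }
      truth <- planted[, c("drug_id", "subtype", "shift")]
    }
    list(response = drug_response_matrix(z),
         annotation = sample_annotation(line_ids, subtype_per_line),
         truth = truth)
  })
}

#' Configuration for a synthetic expression cohort
#'
#' Baseline expression is log-normal: per-gene log-mean drawn from
#' Normal(baseline_logmean, baseline_logsd), per-sample residual
#' Normal(0, noise_sd) on the log scale, then exponentiated — count-like
#' positive values without modeling sequencing depth. Planted activity adds
#' `shift` on the log scale to every gene of a set in every sample of a
#' subtype.
#'
#' @param n_genes total genes simulated (set genes included).
#' @param n_samples_per_subtype named integer vector, subtype -> samples.
#' @param gene_sets list of [gene_set()]s whose genes are included.
#' @param set_activity data.frame with columns `set`, `subtype`, `shift`
#'   (log units) or NULL.
#' @param baseline_logmean,baseline_logsd baseline log-scale parameters
#'   (defaults 4 and 1: median expression ~ exp(4) = 55 with a spread
#'   typical of normalized count data).
#' @param noise_sd per-sample residual sd on the log scale (default 0.5).
#' @return list of class `ExprSimConfig`.
#' @export
expr_sim_config <- function(n_genes = 500L,
                            n_samples_per_subtype = c(Luminal = 25, Basal = 22, HER2 = 11),
                            gene_sets = list(), set_activity = NULL,
                            baseline_logmean = 4, baseline_logsd = 1,
                            noise_sd = 0.5) {
  if (noise_sd <= 0) stop_sx("noise_sd must be positive")
  set_genes <- unique(unlist(lapply(gene_sets, `[[`, "genes")))
  if (length(set_genes) > n_genes) stop_sx("gene-set genes exceed n_genes")
  if (!is.null(set_activity)) {
    need <- c("set", "subtype", "shift")
    if (!all(need %in% colnames(set_activity))) {
      stop_sx("set_activity needs columns: ", paste(need, collapse = ", "))
    }
    set_names <- vapply(gene_sets, `[[`, "", "name")
    if (!all(set_activity$set %in% set_names)) {
      stop_sx("set_activity references unknown gene set")
    }
    if (!all(set_activity$subtype %in% names(n_samples_per_subtype))) {
      stop_sx("set_activity references unknown subtype")
    }
    if (anyDuplicated(set_activity[, c("set", "subtype")])) {
      stop_sx("contradictory duplicate (set, subtype) shifts")
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_samples_per_subtype = n_samples_per_subtype,
                 gene_sets = gene_sets, set_activity = set_activity,
                 baseline_logmean = baseline_logmean,
                 baseline_logsd = baseline_logsd, noise_sd = noise_sd),
            class = "ExprSimConfig")
}

#' Simulate a subtype-structured expression cohort
#'
#' @param cfg an [expr_sim_config()].
#' @param seed integer seed.
#' @return list with `expression` ([expression_matrix()]), `annotation`
#'   ([sample_annotation()]) and `truth` (the planted set/subtype shifts).
#' @export
simulate_expression <- function(cfg, seed) {
  stopifnot(inherits(cfg, "ExprSimConfig"))
  with_seed(seed, {
    subtypes <- names(cfg$n_samples_per_subtype)
    subtype_per_sample <- rep(subtypes, cfg$n_samples_per_subtype)
    n_samples <- length(subtype_per_sample)
    sample_ids <- sprintf("sample%03d", seq_len(n_samples))

    set_genes <- unique(unlist(lapply(cfg$gene_sets, `[[`, "genes")))
    n_bg <- cfg$n_genes - length(set_genes)
    gene_ids <- c(set_genes,
                  if (n_bg > 0L) sprintf("bg_gene%04d", seq_len(n_bg)))

    log_base <- stats::rnorm(cfg$n_genes, cfg$baseline_logmean, cfg$baseline_logsd)
    logv <- matrix(stats::rnorm(cfg$n_genes * n_samples, 0, cfg$noise_sd),
                   cfg$n_genes, n_samples) + log_base
    dimnames(logv) <- list(gene_ids, sample_ids)

    truth <- data.frame(set = character(0), subtype = character(0),
                        shift = numeric(0), stringsAsFactors = FALSE)
    if (!is.null(cfg$set_activity) && nrow(cfg$set_activity) > 0L) {
      set_names <- vapply(cfg$gene_sets, `[[`, "", "name")
      for (i in seq_len(nrow(cfg$set_activity))) {
        sa <- cfg$set_activity[i, ]
        genes <- cfg$gene_sets[[match(sa$set, set_names)]]$genes
        cols <- subtype_per_sample == sa$subtype
        logv[genes, cols] <- logv[genes, cols] + sa$shift
      }
      truth <- cfg$set_activity[, c("set", "subtype", "shift")]
    }
    list(expression = expression_matrix(exp(logv), value_kind = "normalized"),
         annotation = sample_annotation(sample_ids, subtype_per_sample),
         truth = truth)
  })
}

#' Simulate single-agent and combination dose-response grids
#'
#' Single-agent fraction affected follows the median-effect equation
#' `fa = 1/(1 + (Dm/D)^m)`. Combination cells are constructed per
#' `interaction`: `"sham"` treats the pair as one drug split across the two
#' channels (fa of agent 1's curve at the total dose; requires identical
#' agent parameters), `"loewe_additive"` solves the Loewe additivity
#' equation for fa, and `"synergy"` makes the pair behave as if each dose
#' were multiplied by `synergy_factor` before the additive construction —
#' so the downstream combination index is 1/synergy_factor by design.
#' Gaussian noise (sd `noise_sd`) is added on the fa scale and clamped
#' interior; clamps are logged.
#'
#' @param params1,params2 lists with elements `m` and `Dm` for the agents.
#' @param doses1,doses2 strictly positive single-agent dose ladders.
#' @param combo_pairs data.frame with `agent1_dose`, `agent2_dose` for the
#'   combination cells; default the full checkerboard of the two ladders.
#' @param interaction `"sham"`, `"loewe_additive"` or `"synergy"`.
#' @param synergy_factor dose-potentiation factor f > 0 (synergy mode).
#' @param noise_sd sd of fa noise (0 for noiseless grids).
#' @param seed integer seed.
#' @return data.frame grid with `agent1_dose`, `agent2_dose`, `fa`, plus a
#'   `truth` attribute recording the construction.
#' @export
simulate_dose_response <- function(params1, params2 = params1,
                                   doses1, doses2 = doses1,
                                   combo_pairs = NULL,
                                   interaction = c("sham", "loewe_additive", "synergy"),
                                   synergy_factor = 1, noise_sd = 0, seed = 1L) {
  interaction <- match.arg(interaction)
  for (p in list(params1, params2)) {
    if (p$m <= 0 || p$Dm <= 0) stop_sx("m and Dm must be positive")
  }
  if (any(doses1 <= 0) || any(doses2 <= 0)) stop_sx("doses must be positive")
  if (synergy_factor <= 0) stop_sx("synergy_factor must be positive")
  if (noise_sd < 0) stop_sx("noise_sd must be non-negative")
  if (interaction == "sham" &&
      !(isTRUE(all.equal(params1$m, params2$m)) &&
        isTRUE(all.equal(params1$Dm, params2$Dm)))) {
    stop_sx("sham mode requires identical agent parameters (drug with itself)")
  }
  if (is.null(combo_pairs)) {
    combo_pairs <- expand.grid(agent1_dose = doses1, agent2_dose = doses2)
  }
  me_fa <- function(p, d) 1 / (1 + (p$Dm / d)^p$m)
  loewe_fa <- function(d1, d2) {
    # solve d1/Dx1(fa) + d2/Dx2(fa) = 1; LHS is decreasing in fa
    g <- function(fa) {
      d1 / (params1$Dm * (fa / (1 - fa))^(1 / params1$m)) +
        d2 / (params2$Dm * (fa / (1 - fa))^(1 / params2$m)) - 1
    }
    stats::uniroot(g, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  combo_fa <- switch(interaction,
    sham = me_fa(params1, combo_pairs$agent1_dose + combo_pairs$agent2_dose),
    loewe_additive = mapply(loewe_fa, combo_pairs$agent1_dose,
                            combo_pairs$agent2_dose),
    synergy = mapply(loewe_fa, synergy_factor * combo_pairs$agent1_dose,
                     synergy_factor * combo_pairs$agent2_dose)
  )
  grid <- rbind(
    data.frame(agent1_dose = doses1, agent2_dose = 0,
               fa = me_fa(params1, doses1)),
    data.frame(agent1_dose = 0, agent2_dose = doses2,
               fa = me_fa(params2, doses2)),
    data.frame(agent1_dose = combo_pairs$agent1_dose,
               agent2_dose = combo_pairs$agent2_dose, fa = combo_fa)
  )
  if (noise_sd > 0) {
    grid$fa <- with_seed(seed, grid$fa + stats::rnorm(nrow(grid), 0, noise_sd))
    n_clamp <- sum(grid$fa <= FA_EPS | grid$fa >= 1 - FA_EPS)
    if (n_clamp > 0L) sx_log(n_clamp, " noisy fa value(s) clamped interior")
    grid$fa <- pmin(pmax(grid$fa, FA_EPS), 1 - FA_EPS)
  }
  attr(grid, "truth") <- list(params1 = params1, params2 = params2,
                              interaction = interaction,
                              synergy_factor = synergy_factor,
                              expected_ci = switch(interaction,
                                sham = 1, loewe_additive = 1,
                                synergy = 1 / synergy_factor))
  grid
}

#' Simulate two-group survival data
#'
#' Event times are exponential; group 2's hazard equals `hazard_ratio` times
#' group 1's. Censoring times are independent Uniform(0, b) with b solved so
#' the expected censored fraction in group 1 equals `censor_rate`.
#'
#' @param n_per_group subjects per group.
#' @param hazard_ratio group-2 over group-1 hazard (> 0).
#' @param censor_rate target censored fraction in [0, 1).
#' @param baseline_hazard group-1 hazard (events per month; default 0.05,
#'   median survival ~ 14 months).
#' @param seed integer seed.
#' @return data.frame with `sample_id`, `group` (`"g1"`/`"g2"`), `time`,
#'   `event`, plus a `truth` attribute with the generating parameters.
#' @export
simulate_survival <- function(n_per_group, hazard_ratio, censor_rate = 0,
                              baseline_hazard = 0.05, seed = 1L) {
  if (hazard_ratio <= 0) stop_sx("hazard_ratio must be positive")
  if (censor_rate < 0 || censor_rate >= 1) stop_sx("censor_rate must be in [0, 1)")
  with_seed(seed, {
    n <- 2L * n_per_group
    group <- rep(c("g1", "g2"), each = n_per_group)
    haz <- ifelse(group == "g1", baseline_hazard, baseline_hazard * hazard_ratio)
    t_event <- stats::rexp(n, rate = haz)
    if (censor_rate > 0) {
      # P(C < T) for T ~ Exp(l), C ~ U(0, b) is (1 - exp(-l b))/(l b)
      cens_frac <- function(b, l) (1 - exp(-l * b)) / (l * b)
      b <- stats::uniroot(function(b) cens_frac(b, baseline_hazard) - censor_rate,
                          c(1e-8, 1e8), tol = 1e-10)$root
      t_cens <- stats::runif(n, 0, b)
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    } else {
      event <- rep(1L, n)
      time <- t_event
    }
    out <- data.frame(sample_id = sprintf("subj%04d", seq_len(n)),
                      group = group, time = time, event = event,
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(hazard_ratio = hazard_ratio,
                               censor_rate = censor_rate,
                               baseline_hazard = baseline_hazard)
    out
  })
}
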