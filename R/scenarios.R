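#' Run the full pipeline on one simulated community
#'
#' Collapses haplotypes, summarises species, and computes the two headline
#' contrasts: polymorphism by congener group (with its two-sided Fisher
#' exact p-value) and haplotype sharing by polymorphism status.
#'
#' @param sim A `chplex_sim` object from [simulate_community()].
#' @param min_inversion_len,indel_mode Passed to [collapse_haplotypes()].
#' @return A one-row tibble of replicate-level outcomes.
#' @export
analyze_community <- function(sim, min_inversion_len = 3L,
                              indel_mode = "event") {
  clusters <- collapse_haplotypes(sim$records, min_inversion_len, indel_mode)
  summaries <- summarize_species(clusters, sim$metadata, sim$inventory)
  tab <- polymorphism_contingency(summaries, "all")
  fisher <- fisher_two_sided(tab)
  sharing <- sharing_incidences(clusters, summaries)
  sbp <- sharing_by_polymorphism(summaries, sharing)
  frac <- function(x, n) if (n > 0) x / n else NA_real_
  rate_g1 <- frac(tab["group1", "polymorphic"], sum(tab["group1", ]))
  rate_g2 <- frac(tab["group2", "polymorphic"], sum(tab["group2", ]))
  shared_poly <- frac(sbp["polymorphic", "shared"], sum(sbp["polymorphic", ]))
  shared_mono <- frac(sbp["monomorphic", "shared"], sum(sbp["monomorphic", ]))
  tibble::tibble(
    n_species = sum(tab),
    n_group1 = sum(tab["group1", ]),
    n_group2 = sum(tab["group2", ]),
    n_haplotypes = nrow(clusters),
    rate_g1 = rate_g1,
    rate_g2 = rate_g2,
    rate_diff = rate_g2 - rate_g1,
    fisher_p = fisher$p_two_sided,
    shared_frac_poly = shared_poly,
    shared_frac_mono = shared_mono,
    sharing_assoc = shared_poly - shared_mono
  )
}

#' Contrast incomplete lineage sorting and introgression scenarios
#'
#' Replicates the full pipeline (simulation, haplotype collapsing, species
#' summaries, exact tests) under four scenarios built from a base
#' configuration: `null` (no retention, no introgression), `ils` (retention
#' only), `introgression` (transfer only), and `both`. Replicate seeds are
#' drawn once from `seed` and reused across scenarios, so scenarios are
#' compared on paired communities.
#'
#' Expected signatures: under `null`, the group-contrast Fisher test
#' rejects at its nominal rate at most; under `introgression`, group-2
#' species are more often polymorphic than group-1 species and shared
#' incidences concentrate in polymorphic species; under `ils`, sharing
#' occurs without a systematic group contrast.
#'
#' @param base_config A `chplex_config`; its `ils_retention` and
#'   `intro_rate` define the active scenarios' intensities.
#' @param n_replicates Replicates per scenario (>= 50 recommended for
#'   distributional claims).
#' @param seed Integer seed for the replicate-seed stream.
#' @param scenarios Character subset of
#'   `c("null", "ils", "introgression", "both")`.
#' @return A tibble of class `chplex_scenarios`, one row per (scenario,
#'   replicate); see [glance.chplex_scenarios()] for per-scenario summaries.
#' @export
scenario_suite <- function(base_config, n_replicates = 200L, seed = 1L,
                           scenarios = c("null", "ils", "introgression",
                                         "both")) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  rows <- vector("list", length(scenarios) * n_replicates)
  k <- 0L
  for (sc in scenarios) {
    for (r in seq_len(n_replicates)) {
      cfg <- base_config
      cfg$seed <- rep_seeds[r]
      if (sc %in% c("null", "introgression")) cfg$ils_retention <- 0
      if (sc %in% c("null", "ils")) cfg$intro_rate <- 0
      out <- tryCatch({
        sim <- simulate_community(cfg)
        res <- analyze_community(sim)
        res$n_intro_events <- nrow(sim$truth$events)
        res$n_ancestral_shared <-
          sum(sim$truth$pools$provenance == "ancestral-shared")
        res
      }, error = function(e) {
        chplex_abort(
          paste0("Scenario '", sc, "', replicate ", r, " (seed ",
                 rep_seeds[r], ") failed: ", conditionMessage(e)),
          "chplex_simulation_error")
      })
      k <- k + 1L
      rows[[k]] <- dplyr::mutate(out, scenario = sc, replicate = r,
                                 seed = rep_seeds[r], .before = 1)
    }
  }
  res <- dplyr::bind_rows(rows)
  structure(res, class = c("chplex_scenarios", class(res)),
            n_replicates = n_replicates)
}

#' Per-scenario summary of a scenario suite
#'
#' @param x A `chplex_scenarios` tibble.
#' @param alpha Nominal level for the Fisher rejection-rate column.
#' @param ... Unused.
#' @return One row per scenario: mean group contrast, fraction of
#'   replicates with a positive contrast, Fisher rejection rate, and the
#'   mean sharing-by-polymorphism association.
#' @export
glance.chplex_scenarios <- function(x, alpha = 0.05, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$scenario),
    n_replicates = dplyr::n(),
    mean_rate_g1 = mean(.data$rate_g1, na.rm = TRUE),
    mean_rate_g2 = mean(.data$rate_g2, na.rm = TRUE),
    mean_rate_diff = mean(.data$rate_diff, na.rm = TRUE),
    frac_group2_higher = mean(.data$rate_diff > 0, na.rm = TRUE),
    fisher_reject_rate = mean(.data$fisher_p < alpha, na.rm = TRUE),
    mean_sharing_assoc = mean(.data$sharing_assoc, na.rm = TRUE),
    mean_intro_events = mean(.data$n_intro_events),
    .groups = "drop"
  )
}
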