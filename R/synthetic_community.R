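#' Configuration for the synthetic community generator
#'
#' Captures the statistical structure of a hyperdiverse tree-plot survey:
#' many genera with a skewed species-per-genus distribution, a handful of
#' sequenced individuals per species, a small abiotically dispersed
#' minority, and per-species chloroplast haplotype pools shaped by
#' mutation, retention of ancestral haplotypes (an incomplete-lineage-
#' sorting stand-in) and introgressive transfer between congeners.
#'
#' Distribution laws are solved at configuration time: species per genus
#' follow a truncated power law on `1..max_species_per_genus` whose exponent
#' is chosen so the mean matches `mean_species_per_genus`; individuals per
#' species follow a Poisson truncated to `1..max_individuals_per_species`
#' with rate chosen to match `mean_individuals_per_species`.
#'
#' @param n_genera Number of genera at the site (default 238).
#' @param seq_length Alignment length in columns (default 450, a typical
#'   trnH-psbA spacer length).
#' @param mean_species_per_genus Target mean of the species-per-genus law
#'   (default 2.9).
#' @param max_species_per_genus Upper truncation of that law (default 34).
#' @param mean_individuals_per_species Target mean sequenced individuals per
#'   species (default 3.6).
#' @param max_individuals_per_species Upper truncation (default 11).
#' @param abiotic_fraction Probability that a species is abiotically
#'   dispersed (default 0.13).
#' @param p_unsequenced Probability that a site species is never sequenced
#'   (default 0.33), so congener-group classification must rely on the
#'   inventory rather than the sample.
#' @param theta Expected number of extra segregating haplotypes per species
#'   generated by private mutation (default 0.2).
#' @param divergence Mean number of mutation events separating a species'
#'   base haplotype from the genus ancestor (default 5; always at least 2 so
#'   intended haplotypes stay distinct under the two-difference rule).
#' @param indel_frac Fraction of mutation events realised as short deletions
#'   rather than substitutions (default 0.15).
#' @param ils_retention Probability that a congeneric species pair shares
#'   the ancestral haplotype through retention; implemented as independent
#'   per-species retention of the undiverged ancestral base with probability
#'   `sqrt(ils_retention)`, which leaves within-species diversity untouched.
#' @param intro_rate Expected number of introgression events per ordered
#'   congeneric species pair (default 0.1).
#' @param abiotic_multiplier Factor (>= 1) applied to `intro_rate` when the
#'   recipient species is abiotically dispersed (default 2), reflecting the
#'   greater susceptibility of maternally inherited markers to capture when
#'   seed-mediated gene flow is low.
#' @param noise_rate Probability that a sequenced individual acquires a
#'   one-unit "sequencing-noise" substitution (default 0); injected copies
#'   are constructed so collapsing merges them back into their parent
#'   haplotype and never triggers the species-diagnostic exception.
#' @param haplotype_freq_ratio Geometric decay of haplotype frequencies
#'   within a species' pool (default 0.5; the first pool member is the most
#'   frequent).
#' @param voucher_rate Probability that a sample has a herbarium voucher
#'   (default 0.71).
#' @param seed Integer RNG seed; the whole simulation runs on a single
#'   stream seeded once, so outputs are bit-reproducible.
#' @return A list of class `chplex_config`.
#' @export
simulation_config <- function(n_genera = 238L,
                              seq_length = 450L,
                              mean_species_per_genus = 2.9,
                              max_species_per_genus = 34L,
                              mean_individuals_per_species = 3.6,
                              max_individuals_per_species = 11L,
                              abiotic_fraction = 0.13,
                              p_unsequenced = 0.33,
                              theta = 0.2,
                              divergence = 5,
                              indel_frac = 0.15,
                              ils_retention = 0.1,
                              intro_rate = 0.1,
                              abiotic_multiplier = 2,
                              noise_rate = 0,
                              haplotype_freq_ratio = 0.5,
                              voucher_rate = 0.71,
                              seed = 1L) {
  probs <- c(abiotic_fraction = abiotic_fraction,
             p_unsequenced = p_unsequenced,
             ils_retention = ils_retention, noise_rate = noise_rate,
             voucher_rate = voucher_rate)
  bad <- names(probs)[probs < 0 | probs > 1 | is.na(probs)]
  if (length(bad) > 0) {
    chplex_abort(paste0("Probabilities must lie in [0, 1]: ",
                        paste(bad, collapse = ", ")),
                 "chplex_validation_error")
  }
  if (n_genera < 1 || seq_length < 20) {
    chplex_abort("Need n_genera >= 1 and seq_length >= 20",
                 "chplex_validation_error")
  }
  if (theta < 0 || intro_rate < 0 || abiotic_multiplier < 1 ||
      divergence < 2) {
    chplex_abort(paste0("Require theta >= 0, intro_rate >= 0, ",
                        "abiotic_multiplier >= 1, divergence >= 2"),
                 "chplex_validation_error")
  }
  if (haplotype_freq_ratio <= 0 || haplotype_freq_ratio > 1) {
    chplex_abort("haplotype_freq_ratio must be in (0, 1]",
                 "chplex_validation_error")
  }
  if (mean_species_per_genus <= 1 ||
      mean_species_per_genus >= (1 + max_species_per_genus) / 2) {
    chplex_abort("mean_species_per_genus outside attainable range",
                 "chplex_validation_error")
  }
  if (mean_individuals_per_species <= 1 ||
      mean_individuals_per_species >= max_individuals_per_species) {
    chplex_abort("mean_individuals_per_species outside attainable range",
                 "chplex_validation_error")
  }
  cfg <- list(
    n_genera = as.integer(n_genera),
    seq_length = as.integer(seq_length),
    mean_species_per_genus = mean_species_per_genus,
    max_species_per_genus = as.integer(max_species_per_genus),
    mean_individuals_per_species = mean_individuals_per_species,
    max_individuals_per_species = as.integer(max_individuals_per_species),
    abiotic_fraction = abiotic_fraction,
    p_unsequenced = p_unsequenced,
    theta = theta,
    divergence = divergence,
    indel_frac = indel_frac,
    ils_retention = ils_retention,
    intro_rate = intro_rate,
    abiotic_multiplier = abiotic_multiplier,
    noise_rate = noise_rate,
    haplotype_freq_ratio = haplotype_freq_ratio,
    voucher_rate = voucher_rate,
    seed = as.integer(seed)
  )
  cfg$species_law_pmf <- power_law_pmf(mean_species_per_genus,
                                       cfg$max_species_per_genus)
  cfg$individuals_lambda <- truncated_poisson_rate(
    mean_individuals_per_species, cfg$max_individuals_per_species)
  structure(cfg, class = "chplex_config")
}

# pmf proportional to k^(-s) on 1..kmax with exponent solved for the mean
power_law_pmf <- function(target_mean, kmax) {
  k <- seq_len(kmax)
  mean_at <- function(s) {
    w <- k^(-s)
    sum(w * k) / sum(w)
  }
  s <- uniroot(function(s) mean_at(s) - target_mean, c(0, 12),
               tol = 1e-10)$root
  w <- k^(-s)
  w / sum(w)
}

# Poisson rate such that X | 1 <= X <= kmax has the target mean
truncated_poisson_rate <- function(target_mean, kmax) {
  k <- seq_len(kmax)
  mean_at <- function(lam) {
    w <- stats::dpois(k, lam)
    sum(w * k) / sum(w)
  }
  uniroot(function(lam) mean_at(lam) - target_mean, c(0.01, 3 * kmax),
          tol = 1e-10)$root
}

#' Sample from the generator's component laws
#'
#' These are the exact laws [simulate_community()] draws from, exported so
#' the generator's calibration (species per genus, individuals per species,
#' dispersal class) can be checked by Monte Carlo without building
#' sequences.
#'
#' @param n Number of draws.
#' @param config A `chplex_config` object.
#' @return `rspecies_per_genus` and `rindividuals_per_species` return
#'   integer vectors; `rdispersal` returns raw syndrome labels.
#' @export
rspecies_per_genus <- function(n, config) {
  sample.int(config$max_species_per_genus, n, replace = TRUE,
             prob = config$species_law_pmf)
}

#' @rdname rspecies_per_genus
#' @export
rindividuals_per_species <- function(n, config) {
  k <- seq_len(config$max_individuals_per_species)
  w <- stats::dpois(k, config$individuals_lambda)
  sample(k, n, replace = TRUE, prob = w / sum(w))
}

#' @rdname rspecies_per_genus
#' @export
rdispersal <- function(n, config) {
  abiotic <- runif(n) < config$abiotic_fraction
  out <- character(n)
  n_ab <- sum(abiotic)
  if (n_ab > 0) {
    out[abiotic] <- sample(c("autochorous", "anemochorous", "hydrochorous"),
                           n_ab, replace = TRUE)
  }
  n_bi <- sum(!abiotic)
  if (n_bi > 0) {
    out[!abiotic] <- sample(c("zoochorous", "mixed"), n_bi, replace = TRUE,
                            prob = c(0.9, 0.1))
  }
  out
}

# Apply n_events mutation events to a sequence (character string). Deletion
# events blank out 1-3 contiguous base columns; substitutions change one
# base column. Gap-only sequences cannot arise (>= 20 columns, few events).
mutate_sequence <- function(seq, n_events, indel_frac) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (e in seq_len(n_events)) {
    base_pos <- which(chars %in% bases)
    if (runif(1) < indel_frac && length(base_pos) > 10) {
      len <- sample.int(3L, 1L)
      start <- base_pos[sample.int(length(base_pos), 1L)]
      cols <- start:min(start + len - 1L, length(chars))
      chars[cols[chars[cols] %in% bases]] <- "-"
    } else {
      pos <- base_pos[sample.int(length(base_pos), 1L)]
      chars[pos] <- sample(setdiff(bases, chars[pos]), 1L)
    }
  }
  paste(chars, collapse = "")
}

units_to_all <- function(candidate, registry, min_inversion_len = 3L) {
  if (length(registry) == 0) {
    return(integer(0))
  }
  vapply(registry, function(r) {
    u <- cpp_pairwise_units(candidate, r, min_inversion_len)
    u[["substitutions"]] + u[["indel_events"]] + u[["inversion_events"]]
  }, integer(1))
}

# Draw a new haplotype derived from `parent` that is at least two difference
# units away from every registered haplotype of the genus.
new_haplotype <- function(parent, registry, n_events, indel_frac,
                          max_tries = 100L) {
  for (try in seq_len(max_tries)) {
    cand <- mutate_sequence(parent, max(2L, n_events), indel_frac)
    if (all(units_to_all(cand, registry) >= 2L)) {
      return(cand)
    }
    n_events <- n_events + 1L # separate harder on retry
  }
  chplex_abort("Could not place a haplotype >= 2 units from the registry",
               "chplex_simulation_error")
}

#' Simulate a complete synthetic community dataset
#'
#' Generates aligned sequences, sample metadata, a site inventory and a
#' truth log with the survey's statistical structure (see
#' [simulation_config()]). Per genus: a species count is drawn, a random
#' ancestral sequence is created, and every sequenced species receives a
#' base haplotype that either retains the ancestor (with probability
#' `sqrt(ils_retention)`, so congeneric pairs share it with probability
#' `ils_retention`) or diverges from it by mutation; private mutation then
#' adds `Poisson(theta)` extra haplotypes per species, and introgression
#' copies donor haplotypes into congeneric recipients at `intro_rate` per
#' ordered pair (times `abiotic_multiplier` for abiotic recipients). All
#' intended haplotypes within a genus are kept at least two difference
#' units apart, so the collapsing rule recovers them exactly; optional
#' one-unit noise duplicates exercise the collapsing without ever touching
#' that truth. Individuals sample haplotypes from their species' pool with
#' geometrically decaying frequencies. The inventory records true species
#' counts, including never-sequenced species.
#'
#' Given the same configuration (including seed), output is
#' bit-reproducible.
#'
#' @param config A `chplex_config` object.
#' @return A list of class `chplex_sim`: `records`, `metadata`, `inventory`,
#'   `truth` (list with `pools`, `events`, `assignments`) and `config`.
#' @export
simulate_community <- function(config) {
  if (!inherits(config, "chplex_config")) {
    chplex_abort("config must come from simulation_config()",
                 "chplex_validation_error")
  }
  set.seed(config$seed)
  p_retain <- sqrt(config$ils_retention)
  bases <- c("A", "C", "G", "T")

  records <- vector("list", config$n_genera)
  meta <- vector("list", config$n_genera)
  inventory <- vector("list", config$n_genera)
  pools_log <- vector("list", config$n_genera)
  events_log <- vector("list", config$n_genera)
  assign_log <- vector("list", config$n_genera)

  for (g in seq_len(config$n_genera)) {
    genus <- sprintf("Gen%03d", g)
    s_site <- rspecies_per_genus(1L, config)
    inventory[[g]] <- tibble::tibble(genus = genus,
                                     species_count = as.integer(s_site))
    ancestral <- paste(sample(bases, config$seq_length, replace = TRUE),
                       collapse = "")
    sequenced <- runif(s_site) >= config$p_unsequenced
    if (!any(sequenced)) next
    sp_idx <- which(sequenced)
    sp_names <- sprintf("%s sp%02d", genus, sp_idx)
    dispersal <- rdispersal(length(sp_idx), config)
    abiotic <- dispersal %in% c("autochorous", "anemochorous", "hydrochorous")

    registry <- character(0)   # all intended haplotypes of the genus
    reg_label <- character(0)
    pools <- vector("list", length(sp_idx)) # per species: registry labels
    prov <- vector("list", length(sp_idx))
    donor_of <- vector("list", length(sp_idx))

    register <- function(seqs, label) {
      registry[[length(registry) + 1L]] <<- seqs
      reg_label[[length(reg_label) + 1L]] <<- label
      label
    }
    anc_label <- NA_character_ # lazily registered on first retention

    for (i in seq_along(sp_idx)) {
      if (config$ils_retention > 0 && runif(1) < p_retain) {
        if (is.na(anc_label)) {
          anc_label <- register(ancestral, sprintf("%s-T%02d", genus,
                                                   length(registry) + 1L))
        }
        pools[[i]] <- anc_label
        prov[[i]] <- "ancestral-shared"
      } else {
        n_ev <- max(2L, rpois(1L, config$divergence))
        # the ancestor joins the distance checks even before any retention,
        # so a later-retained ancestral haplotype stays >= 2 units from all
        hap <- new_haplotype(ancestral, unique(c(registry, ancestral)),
                             n_ev, config$indel_frac)
        lab <- register(hap, sprintf("%s-T%02d", genus, length(registry) + 1L))
        pools[[i]] <- lab
        prov[[i]] <- "mutation"
      }
      donor_of[[i]] <- NA_character_
      n_extra <- rpois(1L, config$theta)
      for (e in seq_len(n_extra)) {
        parent <- registry[[match(pools[[i]][1], reg_label)]]
        hap <- new_haplotype(parent, unique(c(registry, ancestral)), 2L,
                             config$indel_frac)
        lab <- register(hap, sprintf("%s-T%02d", genus, length(registry) + 1L))
        pools[[i]] <- c(pools[[i]], lab)
        prov[[i]] <- c(prov[[i]], "mutation")
        donor_of[[i]] <- c(donor_of[[i]], NA_character_)
      }
    }

    # introgression over ordered congeneric pairs, fixed (donor, recipient)
    # order for determinism
    ev_donor <- character(0)
    ev_recipient <- character(0)
    ev_hap <- character(0)
    if (length(sp_idx) >= 2 && config$intro_rate > 0) {
      for (d in seq_along(sp_idx)) {
        for (r in seq_along(sp_idx)) {
          if (d == r) next
          rate <- config$intro_rate *
            (if (abiotic[r]) config$abiotic_multiplier else 1)
          n_ev <- rpois(1L, rate)
          for (e in seq_len(n_ev)) {
            lab <- pools[[d]][sample.int(length(pools[[d]]), 1L)]
            ev_donor <- c(ev_donor, sp_names[d])
            ev_recipient <- c(ev_recipient, sp_names[r])
            ev_hap <- c(ev_hap, lab)
            if (!lab %in% pools[[r]]) {
              pools[[r]] <- c(pools[[r]], lab)
              prov[[r]] <- c(prov[[r]], "introgressed")
              donor_of[[r]] <- c(donor_of[[r]], sp_names[d])
            }
          }
        }
      }
    }
    events_log[[g]] <- if (length(ev_hap) > 0) {
      tibble::tibble(type = "introgression", genus = genus, donor = ev_donor,
                     recipient = ev_recipient, haplotype = ev_hap)
    } else NULL

    pools_log[[g]] <- tibble::tibble(
      genus = genus,
      species = rep(sp_names, vapply(pools, length, integer(1))),
      haplotype = unlist(pools),
      provenance = unlist(prov),
      donor = unlist(donor_of)
    )

    # individuals sample from the pool with geometric frequencies
    all_ids <- character(0)
    all_species <- character(0)
    all_seqs <- character(0)
    all_labs <- character(0)
    all_disp <- character(0)
    all_vouch <- logical(0)
    for (i in seq_along(sp_idx)) {
      n_ind <- rindividuals_per_species(1L, config)
      w <- config$haplotype_freq_ratio^(seq_along(pools[[i]]) - 1L)
      draw <- sample(seq_along(pools[[i]]), n_ind, replace = TRUE,
                     prob = w / sum(w))
      labs <- pools[[i]][draw]
      seqs <- registry[match(labs, reg_label)]
      ids <- sprintf("%s_sp%02d_%02d", genus, sp_idx[i], seq_len(n_ind))

      if (config$noise_rate > 0) {
        for (j in seq_len(n_ind)) {
          if (runif(1) >= config$noise_rate) next
          # only perturb when another individual keeps the parent haplotype,
          # so the variant is never fixed in the species (no diagnostic split)
          if (sum(labs == labs[j]) < 2L) next
          noisy <- perturb_one_unit(seqs[j], registry, reg_label, labs[j])
          if (!is.null(noisy)) seqs[j] <- noisy
        }
      }

      all_ids <- c(all_ids, ids)
      all_species <- c(all_species, rep(sp_names[i], n_ind))
      all_seqs <- c(all_seqs, seqs)
      all_labs <- c(all_labs, labs)
      all_disp <- c(all_disp, rep(dispersal[i], n_ind))
      all_vouch <- c(all_vouch, runif(n_ind) < config$voucher_rate)
    }
    records[[g]] <- tibble::tibble(sample_id = all_ids, genus = genus,
                                   species = all_species, residues = all_seqs)
    meta[[g]] <- tibble::tibble(sample_id = all_ids, genus = genus,
                                species = all_species,
                                dispersal_raw = all_disp,
                                voucher = all_vouch)
    assign_log[[g]] <- tibble::tibble(sample_id = all_ids, genus = genus,
                                      species = all_species,
                                      true_haplotype = all_labs)
  }

  empty_events <- tibble::tibble(type = character(), genus = character(),
                                 donor = character(), recipient = character(),
                                 haplotype = character())
  structure(list(
    records = dplyr::bind_rows(records),
    metadata = dplyr::bind_rows(meta),
    inventory = dplyr::bind_rows(inventory),
    truth = list(
      pools = dplyr::bind_rows(pools_log),
      events = {
        e <- dplyr::bind_rows(events_log)
        if (nrow(e) == 0) empty_events else e
      },
      assignments = dplyr::bind_rows(assign_log)
    ),
    config = config
  ), class = "chplex_sim")
}

# One-unit substitution noise that cannot bridge distinct haplotypes: the
# perturbed copy stays >= 2 units from every registered haplotype except its
# parent (distance exactly 1).
perturb_one_unit <- function(seq, registry, reg_label, parent_label,
                             max_tries = 20L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  base_pos <- which(chars %in% bases)
  others <- registry[reg_label != parent_label]
  for (try in seq_len(max_tries)) {
    pos <- base_pos[sample.int(length(base_pos), 1L)]
    cand_chars <- chars
    cand_chars[pos] <- sample(setdiff(bases, chars[pos]), 1L)
    cand <- paste(cand_chars, collapse = "")
    if (all(units_to_all(cand, others) >= 2L)) {
      return(cand)
    }
  }
  NULL
}

#' @export
print.chplex_sim <- function(x, ...) {
  cat("Synthetic community dataset\n")
  cat("  genera (site):", x$config$n_genera,
      " sequenced samples:", nrow(x$records), "\n")
  cat("  sequenced species:", dplyr::n_distinct(x$metadata$species),
      " introgression events:", nrow(x$truth$events), "\n")
  invisible(x)
}

#' Write a simulated community to disk in pipeline input formats
#'
#' Emits one aligned FASTA per genus plus `metadata.tsv`, `inventory.tsv`,
#' `truth_pools.tsv` and `truth_events.tsv`. Outputs are byte-stable for a
#' given simulation.
#'
#' @param sim A `chplex_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in unique(sim$records$genus)) {
    write_alignment_fasta(sim$records[sim$records$genus == g, ],
                          file.path(dir, paste0(g, ".fasta")))
  }
  write_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  write_inventory(sim$inventory, file.path(dir, "inventory.tsv"))
  readr::write_tsv(sim$truth$pools, file.path(dir, "truth_pools.tsv"),
                   quote = "none")
  readr::write_tsv(sim$truth$events, file.path(dir, "truth_events.tsv"),
                   quote = "none")
  invisible(dir)
}
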