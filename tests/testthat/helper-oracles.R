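# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use different algorithms from the
# package: inversion windows come from a palindromic dynamic programme over
# all column windows, clustering from boolean-matrix transitive closure,
# and Fisher p-values from explicit enumeration with choose().

ORACLE_BASES <- c("A", "C", "G", "T")
ORACLE_COMP <- c(A = "T", T = "A", C = "G", G = "C")

# all maximal reverse-complement windows (1-based inclusive) via DP:
# W[i,j] true iff b[i..j] == revcomp(a[i..j]) on clean columns
oracle_inversions <- function(a, b, min_len = 3) {
  A <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  B <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  L <- length(A)
  clean <- A %in% ORACLE_BASES & B %in% ORACLE_BASES
  compA <- unname(ORACLE_COMP[A])
  compA[is.na(compA)] <- "?"
  D <- outer(B, compA, "==") & outer(clean, clean, "&")
  mism <- clean & A != B
  mism_cum <- cumsum(mism)

  # W[[g+1]][i] = window [i, i+g] is a revcomp match
  W <- vector("list", L)
  W[[1]] <- diag(D)                       # g = 0
  if (L >= 2) {
    i <- seq_len(L - 1)
    W[[2]] <- D[cbind(i, i + 1)] & D[cbind(i + 1, i)]
  }
  if (L >= 3) {
    for (g in 2:(L - 1)) {
      i <- seq_len(L - g)
      W[[g + 1]] <- D[cbind(i, i + g)] & D[cbind(i + g, i)] &
        W[[g - 1]][i + 1]
    }
  }

  has_mism <- function(i, j) (mism_cum[j] - if (i > 1) mism_cum[i - 1] else 0) > 0
  valid <- function(i, j) {
    j <= L && i >= 1 && (j - i + 1) >= min_len && W[[j - i + 1]][i] &&
      has_mism(i, j)
  }
  cand <- list()
  if (min_len > L) return(matrix(integer(0), ncol = 2))
  for (g in (min_len - 1):(L - 1)) {
    for (i in seq_len(L - g)) {
      j <- i + g
      if (!valid(i, j)) next
      # maximal: not extendable on its own anti-diagonal
      if (i - 1 >= 1 && j + 1 <= L && (j + 1 - (i - 1) + 1) <= L &&
          W[[j - i + 3]][i - 1] && has_mism(i - 1, j + 1)) next
      cand[[length(cand) + 1]] <- c(i, j)
    }
  }
  if (length(cand) == 0) {
    return(matrix(integer(0), ncol = 2))
  }
  m <- do.call(rbind, cand)
  m <- m[order(m[, 1], -(m[, 2] - m[, 1])), , drop = FALSE]
  keep <- integer(0)
  last_end <- 0
  for (r in seq_len(nrow(m))) {
    if (m[r, 1] > last_end) {
      keep <- c(keep, r)
      last_end <- m[r, 2]
    }
  }
  m[keep, , drop = FALSE]
}

oracle_units <- function(a, b, min_len = 3, mode = "event") {
  A <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  B <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  inv <- oracle_inversions(a, b, min_len)
  in_inv <- logical(length(A))
  for (r in seq_len(nrow(inv))) in_inv[inv[r, 1]:inv[r, 2]] <- TRUE

  base_a <- A %in% ORACLE_BASES
  base_b <- B %in% ORACLE_BASES
  gap_a <- A == "-"
  gap_b <- B == "-"
  transparent <- (gap_a & gap_b) | (!base_a & !gap_a) | (!base_b & !gap_b)
  subs <- sum(base_a & base_b & A != B & !in_inv)
  # indel runs on the column sequence with transparent columns dropped
  kept <- which(!transparent)
  indel_col <- (gap_a & base_b) | (gap_b & base_a)
  runs <- rle(indel_col[kept])
  indel_events <- sum(runs$values)
  indel_sites <- sum(indel_col)
  indel <- if (mode == "event") indel_events else indel_sites
  c(substitutions = subs, indel_events = indel,
    inversion_events = nrow(inv),
    total = subs + indel + nrow(inv))
}

# single-linkage components of the <=1-unit graph via transitive closure
oracle_components <- function(seqs, min_len = 3, mode = "event") {
  n <- length(seqs)
  adj <- diag(n) > 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        d <- oracle_units(seqs[i], seqs[j], min_len, mode)[["total"]]
        adj[i, j] <- adj[j, i] <- d <= 1
      }
    }
  }
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  nc <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      nc <- nc + 1
      comp[reach[i, ]] <- nc
    }
  }
  comp
}

# canonical form of a partition of ids for comparison
canonical_partition <- function(ids, labels) {
  parts <- split(ids, labels)
  parts <- lapply(parts, sort)
  unname(parts[order(vapply(parts, `[`, character(1), 1))])
}

# two-sided Fisher by explicit enumeration over fixed-margin tables
oracle_fisher <- function(tab) {
  m <- tab[1, 1] + tab[1, 2]
  n <- tab[2, 1] + tab[2, 2]
  k <- tab[1, 1] + tab[2, 1]
  if (m + n == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- probs[support == tab[1, 1]]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# species summaries whose genus sizes and polymorphism counts are chosen
# freely; filler genera stay below the scan threshold
scan_summaries <- function(genus_n, genus_k, total, total_poly) {
  stopifnot(sum(genus_n) <= total, sum(genus_k) <= total_poly)
  rows <- list()
  for (i in seq_along(genus_n)) {
    g <- sprintf("Scan%02d", i)
    rows[[i]] <- tibble::tibble(
      genus = g,
      species = sprintf("%s sp%02d", g, seq_len(genus_n[i])),
      n_individuals = 2L, n_haplotypes = 1L, excluded = FALSE,
      polymorphic = seq_len(genus_n[i]) <= genus_k[i],
      group = 2L, dispersal_class = "biotic")
  }
  fill_n <- total - sum(genus_n)
  fill_k <- total_poly - sum(genus_k)
  i <- 0
  while (fill_n > 0) {
    i <- i + 1
    g <- sprintf("Fill%03d", i)
    n_here <- min(7L, fill_n)
    k_here <- min(n_here, fill_k)
    rows[[length(rows) + 1]] <- tibble::tibble(
      genus = g, species = sprintf("%s sp%02d", g, seq_len(n_here)),
      n_individuals = 2L, n_haplotypes = 1L, excluded = FALSE,
      polymorphic = seq_len(n_here) <= k_here,
      group = 2L, dispersal_class = "biotic")
    fill_n <- fill_n - n_here
    fill_k <- fill_k - k_here
  }
  dplyr::bind_rows(rows)
}

# haplotype label of each id according to a cluster table
cluster_membership_of <- function(clusters, ids) {
  long <- chplex::cluster_members(clusters)
  long$haplotype_id[match(ids, long$sample_id)]
}

make_records <- function(sample_id, genus, species, residues) {
  tibble::tibble(sample_id = sample_id, genus = genus, species = species,
                 residues = residues)
}

random_seq <- function(L) paste(sample(ORACLE_BASES, L, replace = TRUE),
                                collapse = "")

# random genus for oracle comparisons: sequences derived from a common base
# by substitutions, short deletions and occasional reverse-complement
# inversions, so all three difference classes are exercised
random_oracle_genus <- function(n_seq, L) {
  base <- strsplit(random_seq(L), "", fixed = TRUE)[[1]]
  seqs <- character(n_seq)
  for (i in seq_len(n_seq)) {
    chars <- base
    for (e in seq_len(sample(0:3, 1))) {
      kind <- sample(c("sub", "indel", "inv"), 1, prob = c(0.5, 0.3, 0.2))
      if (kind == "sub") {
        pos <- sample(which(chars %in% ORACLE_BASES), 1)
        chars[pos] <- sample(setdiff(ORACLE_BASES, chars[pos]), 1)
      } else if (kind == "indel") {
        len <- sample(1:4, 1)
        start <- sample(seq_len(L - len), 1)
        cols <- start:(start + len - 1)
        chars[cols] <- "-"
      } else {
        len <- sample(3:6, 1)
        start <- sample(seq_len(L - len), 1)
        cols <- start:(start + len - 1)
        seg <- chars[cols]
        if (all(seg %in% ORACLE_BASES)) {
          chars[cols] <- rev(unname(ORACLE_COMP[seg]))
        }
      }
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

# deterministic polymorphism fixture over an {A,C} alphabet (reverse
# complements live in {G,T}, so no inversion can ever be detected and
# distances are pure Hamming counts)
ac_base <- function(L = 40) paste(rep(c("A", "C"), length.out = L),
                                  collapse = "")

ac_variant <- function(base, positions) {
  chars <- strsplit(base, "", fixed = TRUE)[[1]]
  chars[positions] <- ifelse(chars[positions] == "A", "C", "A")
  paste(chars, collapse = "")
}

# community whose included-species counts per stratum/group/polymorphism
# cell can be chosen freely; every species contributes two individuals
build_count_community <- function(cells) {
  # cells: tibble with columns dispersal ("abiotic"/"biotic"), group (1|2),
  # n_poly, n_total
  base <- ac_base(40)
  records <- list()
  metadata <- list()
  inventory <- list()
  g_idx <- 0
  for (r in seq_len(nrow(cells))) {
    n_total <- cells$n_total[r]
    n_poly <- cells$n_poly[r]
    disp <- if (cells$dispersal[r] == "abiotic") "anemochorous" else "zoochorous"
    per_genus <- if (cells$group[r] == 1) 1L else 2L
    sp_done <- 0
    while (sp_done < n_total) {
      g_idx <- g_idx + 1
      genus <- sprintf("Fix%04d", g_idx)
      n_here <- min(per_genus, n_total - sp_done)
      inventory[[length(inventory) + 1]] <- tibble::tibble(
        genus = genus,
        species_count = if (cells$group[r] == 1) 1L else 2L)
      for (s in seq_len(n_here)) {
        sp_done <- sp_done + 1
        species <- sprintf("%s sp%d", genus, s)
        hap1 <- if (s == 1) base else ac_variant(base, c(1, 2))
        poly <- sp_done <= n_poly
        seqs <- if (poly) c(hap1, ac_variant(hap1, c(5, 6))) else c(hap1, hap1)
        ids <- sprintf("%s_s%d_%d", genus, s, 1:2)
        records[[length(records) + 1]] <- make_records(ids, genus, species,
                                                       seqs)
        metadata[[length(metadata) + 1]] <- tibble::tibble(
          sample_id = ids, genus = genus, species = species,
          dispersal_raw = disp, voucher = TRUE)
      }
    }
  }
  list(records = dplyr::bind_rows(records),
       metadata = dplyr::bind_rows(metadata),
       inventory = dplyr::bind_rows(inventory))
}
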