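with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# random A/C/G/T string with an exact G+C count
random_dna <- function(n, gc = 0.4, gc_count = NULL) {
  gc_count <- gc_count %||% round(n * gc)
  stopifnot(gc_count >= 0, gc_count <= n)
  chars <- character(n)
  gc_pos <- sample.int(n, gc_count)
  chars[gc_pos] <- sample(c("G", "C"), gc_count, replace = TRUE)
  chars[-gc_pos] <- sample(c("A", "T"), n - gc_count, replace = TRUE)
  if (gc_count == n) chars <- sample(c("G", "C"), n, replace = TRUE)
  paste(chars, collapse = "")
}

# deterministic concrete instance of a degenerate primer: first
# lexicographic base at every ambiguous position
concrete_variant <- function(primer) {
  chars <- check_primer_seq(get_primer(primer))
  paste(vapply(chars, function(ch) sort(IUPAC_SETS[[ch]])[[1L]],
               character(1L)), collapse = "")
}

#' Two-state melt model parameters
#'
#' Parameters of the simulator's fluorescence model
#' `F(T) = b0 + b1 * T + A * theta(T) + noise`, with helicity
#' `theta(T) = 1 / (1 + exp((T - Tm) / s))`. The transition width `s`
#' (default 0.6 degrees C) controls melt-peak sharpness; the peak of
#' -dF/dT sits exactly at Tm for this model. Fluorescence is on a
#' normalized scale with unit amplitude; everything downstream is
#' scale-equivariant, so the absolute RFU scale is immaterial.
#'
#' @param width Transition width s in degrees C (> 0, default 0.6).
#' @param baseline_intercept,baseline_slope Linear background `b0 + b1*T`
#'   (defaults 2 and -0.01 RFU/degree C, a mild downward dye drift).
#' @param amplitude Helicity amplitude A in RFU (> 0, default 1).
#' @param noise_sd Gaussian noise SD per well and temperature step
#'   (default 0.002 RFU).
#' @param na_molar Monovalent salt concentration used when Tm is
#'   derived from a sequence (default 0.05 mol/L).
#' @return A `melt_params` list.
#' @export
melt_params <- function(width = 0.6, baseline_intercept = 2,
                        baseline_slope = -0.01, amplitude = 1,
                        noise_sd = 0.002, na_molar = 0.05) {
  stopifnot(width > 0, amplitude > 0, noise_sd >= 0, na_molar > 0)
  structure(list(width = width, baseline_intercept = baseline_intercept,
                 baseline_slope = baseline_slope, amplitude = amplitude,
                 noise_sd = noise_sd, na_molar = na_molar),
            class = "melt_params")
}

#' Empirical amplicon melting temperature
#'
#' The simulator's definition of an amplicon's Tm: the classic
#' salt-adjusted GC/length rule
#' `Tm = 81.5 + 16.6 * log10([Na+]) + 0.41 * GC% - 600 / N`,
#' with GC% in percent and N the product length in bases. This is the
#' model's *definition*, not a physical prediction of real amplicon
#' melts; by construction A<->T and G<->C substitutions are Tm-neutral,
#' which is the mechanism behind indistinguishable haplotype groups.
#'
#' @param sequence A/C/G/T string, length >= 20. At most 10 percent
#'   ambiguous bases; GC% is computed over unambiguous bases.
#' @param na_molar Monovalent salt concentration in mol/L (default
#'   0.05).
#' @return Tm in degrees C.
#' @export
#' @examples
#' amplicon_tm(strrep("GCGCA", 20))  # 100-mer, 80% GC
amplicon_tm <- function(sequence, na_molar = 0.05) {
  stopifnot(na_molar > 0)
  n <- nchar(sequence)
  if (n < 20L) stop("sequence shorter than 20 bases", call. = FALSE)
  chars <- strsplit(toupper(sequence), "")[[1L]]
  ambig <- !chars %in% c("A", "C", "G", "T")
  if (mean(ambig) > 0.1) {
    stop("more than 10% ambiguous bases in sequence", call. = FALSE)
  }
  gc_pct <- 100 * mean(chars[!ambig] %in% c("G", "C"))
  81.5 + 16.6 * log10(na_molar) + 0.41 * gc_pct - 600 / n
}

#' Simulate COI-like template sequences with planted haplotype structure
#'
#' Per species, a random inter-primer core at the target GC content is
#' flanked by one concrete expansion of the EW_COI_F2 forward primer
#' and the reverse complement of an EW_COI_R1 expansion, plus random
#' flanks — so every template yields exactly one 158-bp product with
#' that primer pair (23 + 115 + 20 with the default core length).
#' Additional haplotypes within a species are derived from the base
#' core by point substitutions at distinct sites; a configurable
#' fraction are GC-neutral (A<->T or G<->C), which leaves the model Tm
#' unchanged and therefore produces melt-indistinguishable haplotypes.
#'
#' @param n_species Number of species (default 8).
#' @param n_haplotypes Haplotypes per species, scalar or vector
#'   (default 1).
#' @param substitutions Substitutions separating each extra haplotype
#'   from the species base core (default 1).
#' @param core_length Inter-primer core length in bases (default 115).
#' @param gc_target Core GC fraction in (0, 1) (default 0.4).
#' @param species_gc_counts Optional integer vector of exact core G+C
#'   counts per species, for controlled Tm spacing.
#' @param gc_neutral_fraction Probability that a substitution is
#'   GC-neutral (default 0.5).
#' @param flank Random flank length on each side (default 30).
#' @param seed Optional RNG seed (same seed, byte-identical output).
#' @return Tibble with one row per template: `label`, `species`,
#'   `haplotype`, `sequence`, and list columns `sites` / `neutral`
#'   recording the planted substitutions (the truth table).
#' @export
simulate_sequences <- function(n_species = 8L, n_haplotypes = 1L,
                               substitutions = 1L, core_length = 115L,
                               gc_target = 0.4, species_gc_counts = NULL,
                               gc_neutral_fraction = 0.5, flank = 30L,
                               seed = NULL) {
  stopifnot(n_species >= 1L, all(n_haplotypes >= 1L), substitutions >= 1L,
            gc_target > 0, gc_target < 1)
  n_haplotypes <- rep_len(n_haplotypes, n_species)
  if (core_length < substitutions * max(n_haplotypes)) {
    stop("core shorter than the total number of planted substitutions",
         call. = FALSE)
  }
  with_seed_maybe(seed, {
    f2 <- concrete_variant("EW_COI_F2")
    r1rc <- revcomp(concrete_variant("EW_COI_R1"))
    rows <- list()
    for (i in seq_len(n_species)) {
      core <- random_dna(core_length, gc = gc_target,
                         gc_count = species_gc_counts[i])
      left <- random_dna(flank, gc = gc_target)
      right <- random_dna(flank, gc = gc_target)
      free_sites <- sample(seq_len(core_length))  # shuffled, drawn without reuse
      used <- 0L
      for (h in seq_len(n_haplotypes[[i]])) {
        hap_core <- core
        sites <- integer(0)
        neutral <- logical(0)
        if (h > 1L) {
          sites <- free_sites[used + seq_len(substitutions)]
          used <- used + substitutions
          neutral <- stats::runif(substitutions) < gc_neutral_fraction
          for (k in seq_along(sites)) {
            hap_core <- substitute_base(hap_core, sites[[k]], neutral[[k]])
          }
        }
        rows[[length(rows) + 1L]] <- tibble(
          label = sprintf("species_%02d_h%d", i, h),
          species = sprintf("species_%02d", i),
          haplotype = h,
          sequence = paste0(left, f2, hap_core, r1rc, right),
          sites = list(sites),
          neutral = list(neutral)
        )
      }
    }
    bind_rows(rows)
  })
}

# point substitution at 1-based core position; neutral keeps the GC count
substitute_base <- function(core, site, neutral) {
  base <- substr(core, site, site)
  swap <- c(A = "T", T = "A", G = "C", C = "G")
  new <- if (neutral) {
    swap[[base]]
  } else if (base %in% c("A", "T")) {
    sample(c("G", "C"), 1L)
  } else {
    sample(c("A", "T"), 1L)
  }
  substr(core, site, site) <- new
  core
}

#' Simulate a raw melt-fluorescence plate
#'
#' Generates raw RFU series on a temperature ramp (default 65 to 95
#' degrees C in 0.1 steps, 301 points) from the two-state model of
#' [melt_params()], with independent Gaussian noise per well and
#' temperature step and the requested number of technical replicates
#' per label (default 5).
#'
#' @param tms Amplicon Tms: a named numeric vector (`label` -> Tm), or
#'   a tibble with `label` and either `tm` or `sequence` (Tm then
#'   computed by [amplicon_tm()]).
#' @param params A [melt_params()] object.
#' @param replicates Technical replicates per label (default 5).
#' @param grid Strictly increasing temperature grid (default
#'   `seq(65, 95, by = 0.1)`).
#' @param role Role recorded for every well (default `"reference"`).
#' @param seed Optional RNG seed.
#' @return List with `data` (long melt tibble: `sample_id`, `label`,
#'   `replicate_group`, `role`, `temperature`, `rfu`) and `truth`
#'   (tibble `sample_id`, `label`, `tm`, `replicate`).
#' @export
simulate_melt_plate <- function(tms, params = melt_params(), replicates = 5L,
                                grid = seq(65, 95, by = 0.1),
                                role = "reference", seed = NULL) {
  stopifnot(inherits(params, "melt_params"), replicates >= 1L)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing",
                                 call. = FALSE)
  if (is.data.frame(tms)) {
    if ("tm" %in% names(tms)) {
      tmv <- setNames(tms$tm, tms$label)
    } else if ("sequence" %in% names(tms)) {
      tmv <- setNames(
        vapply(tms$sequence, amplicon_tm, numeric(1L),
               na_molar = params$na_molar, USE.NAMES = FALSE),
        tms$label)
    } else {
      stop("tms tibble needs a 'tm' or 'sequence' column", call. = FALSE)
    }
  } else {
    tmv <- tms
    if (is.null(names(tmv))) stop("tms vector must be named", call. = FALSE)
  }
  out_of_range <- tmv < min(grid) | tmv > max(grid)
  if (any(out_of_range)) {
    warning("Tm outside the temperature grid for: ",
            paste(names(tmv)[out_of_range], collapse = ", "),
            " (curve may have no interior peak)", call. = FALSE)
  }
  with_seed_maybe(seed, {
    wells <- list()
    truth <- list()
    for (lab in names(tmv)) {
      for (r in seq_len(replicates)) {
        theta <- 1 / (1 + exp((grid - tmv[[lab]]) / params$width))
        f <- params$baseline_intercept + params$baseline_slope * grid +
          params$amplitude * theta +
          rnorm(length(grid), sd = params$noise_sd)
        id <- if (replicates == 1L) lab else sprintf("%s_r%d", lab, r)
        wells[[length(wells) + 1L]] <- tibble(
          sample_id = id, label = lab, replicate_group = lab, role = role,
          temperature = grid, rfu = f)
        truth[[length(truth) + 1L]] <- tibble(
          sample_id = id, label = lab, tm = tmv[[lab]], replicate = r)
      }
    }
    list(data = bind_rows(wells), truth = bind_rows(truth))
  })
}

#' Synthetic COI-like reference template carrying all six EW primer sites
#'
#' Builds a single synthetic template on which the nine EW_COI primer
#' combinations reproduce the assay's product-length table: forward
#' sites (F3, F1, F2) and reverse sites (R3, R1, R2) are planted at
#' offsets solved from the published lengths (F2 x R1 = 158 bp,
#' F1 x R1 = 194 bp, F3 x R2 = 386 bp, ...), with random filler
#' sequence between the sites. A stand-in for a GenBank COI reference
#' when no network is available; it is synthetic and carries no real
#' earthworm sequence.
#'
#' @param seed RNG seed for the filler sequence (default 1).
#' @param gc_target Filler GC fraction (default 0.4).
#' @return Tibble (`label`, `sequence`) with one row,
#'   label `"synthetic_coi_reference"`.
#' @export
simulate_coi_reference <- function(seed = 1L, gc_target = 0.4) {
  with_seed_maybe(seed, {
    f1 <- concrete_variant("EW_COI_F1")
    f2 <- concrete_variant("EW_COI_F2")
    f3 <- concrete_variant("EW_COI_F3")
    r1 <- revcomp(concrete_variant("EW_COI_R1"))
    r2 <- revcomp(concrete_variant("EW_COI_R2"))
    r3 <- revcomp(concrete_variant("EW_COI_R3"))
    # fwd starts (F3, F1, F2) and rev ends (R3, R1, R2) relative to F3 = 0,
    # solved from the nine published product lengths
    segs <- c(
      f3,                    # [0, 20)
      random_dna(79, gc_target),   # [20, 99)
      f1,                    # [99, 122)
      random_dna(13, gc_target),   # [122, 135)
      f2,                    # [135, 158)
      random_dna(70, gc_target),   # [158, 228)
      r3,                    # [228, 251)
      random_dna(22, gc_target),   # [251, 273)
      r1,                    # [273, 293)
      random_dna(71, gc_target),   # [293, 364)
      r2                     # [364, 386)
    )
    body <- paste(segs, collapse = "")
    stopifnot(nchar(body) == 386L)
    tibble(
      label = "synthetic_coi_reference",
      sequence = paste0(random_dna(25, gc_target), body,
                        random_dna(25, gc_target))
    )
  })
}

# group -> haplotype mapping used by the chlorotica_haplotypes scenario:
# group 1 = {h1}; group 2 = {h2, h3, h6, h7}; group 3 = {h4, h5, h8}
chlorotica_truth_map <- c(`1` = 1L, `2` = 2L, `3` = 2L, `4` = 3L, `5` = 3L,
                          `6` = 2L, `7` = 2L, `8` = 3L)

#' Generate a complete named test scenario
#'
#' Builds everything a pipeline run consumes — sequences, raw melt
#' plate(s), sample sheet and truth table — for one of three planted
#' scenarios:
#'
#' * `"eight_species"`: 8 species with core GC contents stepped so
#'   that consecutive model Tms differ by about 0.78 degrees C; a
#'   reference plate (5 replicates per species) plus 200 single-well
#'   unknown queries (25 per species).
#' * `"caliginosa_longa_ambiguity"`: two labels whose main-assay Tms
#'   differ by 0.04 degrees C (below the 0.1 ramp resolution), so they
#'   classify as ambiguous; plus one multiplex well per query whose Tm
#'   comes from the species-specific multiplex product (116-bp 16S
#'   product for *caliginosa*-truth queries, 213-bp COI product for
#'   *longa*-truth), landing in disjoint Tm windows.
#' * `"chlorotica_haplotypes"`: 28 individuals carrying 8 planted
#'   haplotypes of one species; within-group haplotypes differ only by
#'   GC-neutral substitutions (identical model Tm), between-group
#'   cores differ by +3 / +7 G+C, so the 8 haplotypes collapse into 3
#'   melt-distinguishable groups with mapping group1 = \{h1\},
#'   group2 = \{h2, h3, h6, h7\}, group3 = \{h4, h5, h8\}.
#'
#' @param scenario One of the three names above.
#' @param seed RNG seed (default 1; identical seeds give identical
#'   fixtures).
#' @param dir Optional directory; when given, writes `melt.csv`,
#'   `samples.csv`, `seqs.fasta`, `truth.tsv` (and `multiplex.csv`
#'   where applicable) and returns the paths in the result.
#' @param replicates Technical replicates per reference label
#'   (default 5).
#' @return A list whose elements depend on the scenario; always
#'   contains `melt` (long tibble), `sheet`, `truth`, and `sequences`
#'   where sequences are part of the scenario.
#' @export
make_fixture <- function(scenario = c("eight_species",
                                      "caliginosa_longa_ambiguity",
                                      "chlorotica_haplotypes"),
                         seed = 1L, dir = NULL, replicates = 5L) {
  scenario <- match.arg(scenario)
  fx <- with_seed_maybe(seed, switch(
    scenario,
    eight_species = fixture_eight_species(replicates),
    caliginosa_longa_ambiguity = fixture_cal_longa(replicates),
    chlorotica_haplotypes = fixture_chlorotica(replicates)
  ))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(melt = file.path(dir, "melt.csv"),
                  sheet = file.path(dir, "samples.csv"),
                  truth = file.path(dir, "truth.tsv"))
    write_melt_table(fx$melt, paths$melt)
    utils::write.table(fx$sheet, paths$sheet, sep = ",", row.names = FALSE,
                       quote = FALSE)
    truth_flat <- fx$truth[vapply(fx$truth, Negate(is.list), logical(1L))]
    utils::write.table(truth_flat, paths$truth, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    if (!is.null(fx$sequences)) {
      paths$fasta <- file.path(dir, "seqs.fasta")
      write_fasta(fx$sequences, paths$fasta)
    }
    if (!is.null(fx$multiplex_melt)) {
      paths$multiplex <- file.path(dir, "multiplex.csv")
      write_melt_table(fx$multiplex_melt, paths$multiplex)
    }
    fx$paths <- paths
  }
  fx
}

sheet_from_melt <- function(melt) {
  distinct(melt, .data$sample_id, .data$label, .data$replicate_group,
           .data$role)
}

fixture_eight_species <- function(replicates) {
  seqs <- simulate_sequences(n_species = 8L, n_haplotypes = 1L,
                             species_gc_counts = 34L + 3L * (0:7))
  seqs$label <- seqs$species  # one haplotype per species
  refs <- simulate_melt_plate(seqs[, c("label", "sequence")],
                              replicates = replicates, role = "reference")
  tmv <- setNames(distinct(refs$truth, .data$label, .data$tm)$tm,
                  distinct(refs$truth, .data$label, .data$tm)$label)
  q_lab <- rep(names(tmv), each = 25L)
  queries <- simulate_melt_plate(setNames(tmv[q_lab],
                                          sprintf("q%03d", seq_along(q_lab))),
                                 replicates = 1L, role = "unknown")
  truth_q <- tibble(sample_id = sprintf("q%03d", seq_along(q_lab)),
                    true_label = q_lab)
  qd <- queries$data
  qd$label <- NA_character_
  melt <- bind_rows(refs$data, qd)
  list(melt = melt, sheet = sheet_from_melt(melt),
       truth = truth_q, ref_truth = refs$truth,
       sequences = seqs[, c("label", "sequence")])
}

fixture_cal_longa <- function(replicates) {
  tm_main <- c(Apo_caliginosa = 76.00, Apo_longa = 76.04)
  t16s <- paste0(get_primer("16S-Ac-F1"), random_dna(76, 0.32),
                 revcomp(get_primer("WORM-16S-R1")))
  tcoi <- paste0(get_primer("COI-Al-F2"), random_dna(173, 0.45),
                 revcomp(get_primer("COI-Al-R2")))
  mtm <- c(Apo_caliginosa = amplicon_tm(t16s), Apo_longa = amplicon_tm(tcoi))
  refs <- simulate_melt_plate(tm_main, replicates = replicates,
                              role = "reference")
  n_q <- 6L
  q_lab <- rep(names(tm_main), each = n_q)
  q_id <- sprintf("q%02d", seq_along(q_lab))
  queries <- simulate_melt_plate(setNames(tm_main[q_lab], q_id),
                                 replicates = 1L, role = "unknown")
  multiplex <- simulate_melt_plate(setNames(mtm[q_lab], q_id),
                                   replicates = 1L, role = "unknown")
  qd <- queries$data
  qd$label <- NA_character_
  melt <- bind_rows(refs$data, qd)
  list(melt = melt, sheet = sheet_from_melt(melt),
       multiplex_melt = multiplex$data,
       truth = tibble(sample_id = q_id, true_label = q_lab,
                      multiplex_tm = unname(mtm[q_lab])),
       sequences = tibble(
         label = c("synthetic_caliginosa_16S", "synthetic_longa_COI"),
         sequence = c(t16s, tcoi)))
}

fixture_chlorotica <- function(replicates) {
  core_len <- 115L
  base <- random_dna(core_len, gc = 0.4)
  chars <- strsplit(base, "")[[1L]]
  at_sites <- sample(which(chars %in% c("A", "T")))
  stopifnot(length(at_sites) >= 15L)
  to_gc <- function(core, sites) {
    for (s in sites) substr(core, s, s) <- sample(c("G", "C"), 1L)
    core
  }
  neutral_at <- function(core, site) substitute_base(core, site, neutral = TRUE)
  g2 <- to_gc(base, at_sites[1:3])
  g3 <- to_gc(base, at_sites[4:10])
  extra <- at_sites[11:14]
  cores <- list(
    h1 = base,
    h2 = g2, h3 = neutral_at(g2, extra[[1L]]),
    h4 = g3, h5 = neutral_at(g3, extra[[2L]]),
    h6 = neutral_at(g2, extra[[3L]]), h7 = neutral_at(g2, extra[[4L]]),
    h8 = neutral_at(g3, at_sites[[15L]])
  )
  f2 <- concrete_variant("EW_COI_F2")
  r1rc <- revcomp(concrete_variant("EW_COI_R1"))
  left <- random_dna(30, 0.4)
  right <- random_dna(30, 0.4)
  amplicon <- function(core) paste0(f2, core, r1rc)
  # individuals ordered so first occurrence matches haplotype numbering
  hap_of_ind <- rep(1:8, times = c(6L, 4L, 3L, 4L, 3L, 3L, 2L, 3L))
  ind <- sprintf("ind%02d", seq_along(hap_of_ind))
  seqs <- tibble(
    label = ind,
    haplotype = hap_of_ind,
    group = unname(chlorotica_truth_map[as.character(hap_of_ind)]),
    sequence = vapply(hap_of_ind,
                      function(h) paste0(left, amplicon(cores[[h]]), right),
                      character(1L))
  )
  tms <- vapply(hap_of_ind, function(h) amplicon_tm(amplicon(cores[[h]])),
                numeric(1L))
  plate <- simulate_melt_plate(setNames(tms, ind), replicates = replicates,
                               role = "unknown")
  melt <- plate$data
  melt$label <- rep(sprintf("h%d", hap_of_ind),
                    each = nrow(melt) / length(ind))
  list(melt = melt, sheet = sheet_from_melt(melt),
       truth = mutate(seqs, tm = tms)[, c("label", "haplotype", "group", "tm")],
       sequences = seqs[, c("label", "sequence")])
}
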