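# IUPAC nucleotide ambiguity sets and complements
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMP <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

check_primer_seq <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad)) {
    stop("invalid IUPAC symbol ", dQuote(chars[[bad[[1L]]]]),
         " at position ", bad[[1L]], call. = FALSE)
  }
  chars
}

#' Reverse complement of an IUPAC DNA string
#'
#' Handles all 15 ambiguity codes (e.g. `R` -> `Y`, `D` -> `H`).
#'
#' @param sequence DNA string, 5' to 3'.
#' @return The reverse complement, 5' to 3'.
#' @export
revcomp <- function(sequence) {
  chars <- check_primer_seq(sequence)
  paste(rev(unname(IUPAC_COMP[chars])), collapse = "")
}

#' Built-in HRM primer registry
#'
#' The degenerate COI primer panel for earthworm HRM identification
#' (three forward, three reverse primers), plus the four multiplex
#' primers used to separate *Aporrectodea caliginosa* (116-bp 16S
#' product) from *Apo. longa* (213-bp COI product).
#'
#' @return A tibble with columns `name`, `sequence` (IUPAC, 5' to 3')
#'   and `role` (`forward`/`reverse`).
#' @export
hrm_primers <- function() {
  tibble(
    name = c("EW_COI_F1", "EW_COI_F2", "EW_COI_F3",
             "EW_COI_R1", "EW_COI_R2", "EW_COI_R3",
             "16S-Ac-F1", "WORM-16S-R1", "COI-Al-F2", "COI-Al-R2"),
    sequence = c(
      "CATGCATTYGTDATAATYTTCTT",
      "GTVTTYATYGGNGGNTTYGGAAA",
      "ATRGTDGGDGCHGGWATRAG",
      "CCDGTHCCDGCNCCYTTTTC",
      "AGAATNAGNGADGGRGGNARNA",
      "GADGCWCCHGCYARRTGDARDGA",
      "CTAAATTCTGACCCTTATTC",
      "CCTAAGCCAACATCGAGGTG",
      "TGGCTTCTACCTCTAATACT",
      "ATGAAGGGAGAAGATGGCCA"
    ),
    role = rep(c("forward", "reverse"), c(3L, 3L)) |>
      c(rep(c("forward", "reverse"), 2L))
  )
}

#' Look up a primer sequence by registry name
#'
#' @param name Primer name from [hrm_primers()], or a raw IUPAC DNA
#'   string (length >= 10), returned as-is.
#' @return The primer sequence string.
#' @export
get_primer <- function(name) {
  reg <- hrm_primers()
  i <- match(name, reg$name)
  if (!is.na(i)) return(reg$sequence[[i]])
  chars <- check_primer_seq(name)
  if (length(chars) < 10L) {
    stop("unknown primer name (and too short to be a sequence): ",
         dQuote(name), call. = FALSE)
  }
  toupper(name)
}

# registry lookup without the length-10 floor (expansion utilities work on
# arbitrary IUPAC strings)
resolve_primer <- function(x) {
  reg <- hrm_primers()
  i <- match(x, reg$name)
  if (!is.na(i)) reg$sequence[[i]] else toupper(x)
}

#' Degeneracy of an IUPAC primer
#'
#' The number of concrete A/C/G/T sequences a degenerate primer
#' expands to: the product over positions of each symbol's set size.
#'
#' @param primer Primer name or IUPAC sequence.
#' @return A single number.
#' @seealso [enumerate_variants()]
#' @export
#' @examples
#' expand_degenerate("ACGT")       # 1
#' expand_degenerate("EW_COI_F2")  # 384
expand_degenerate <- function(primer) {
  chars <- check_primer_seq(resolve_primer(primer))
  prod(vapply(chars, function(ch) length(IUPAC_SETS[[ch]]), numeric(1L)))
}

#' Enumerate the concrete variants of a degenerate primer
#'
#' Expansion in lexicographic order (A < C < G < T, leftmost position
#' most significant). Refused above `max_variants` to avoid accidental
#' combinatorial blow-ups.
#'
#' @param primer Primer name or IUPAC sequence.
#' @param max_variants Enumeration cap (default 1e4).
#' @return Character vector of A/C/G/T sequences.
#' @export
enumerate_variants <- function(primer, max_variants = 1e4) {
  primer <- resolve_primer(primer)
  chars <- check_primer_seq(primer)
  n <- expand_degenerate(primer)
  if (n > max_variants) {
    stop("primer expands to ", n, " variants, above max_variants = ",
         max_variants, call. = FALSE)
  }
  sets <- lapply(chars, function(ch) sort(IUPAC_SETS[[ch]]))
  grid <- rev(expand.grid(rev(sets), stringsAsFactors = FALSE))
  out <- do.call(paste0, grid)
  sort(out)
}

# logical match matrix: rows IUPAC primer symbols, cols template bases
# (A/C/G/T plus N). Conservative mode: template N matches nothing.
# Permissive mode: match when the two IUPAC sets intersect.
iupac_match_matrix <- function(permissive_n = FALSE) {
  tmpl <- c("A", "C", "G", "T", "N")
  m <- matrix(FALSE, nrow = length(IUPAC_SETS), ncol = length(tmpl),
              dimnames = list(names(IUPAC_SETS), tmpl))
  for (p in names(IUPAC_SETS)) {
    for (b in tmpl) {
      m[p, b] <- if (b == "N") {
        permissive_n  # N's set is ACGT, which intersects every primer set
      } else {
        b %in% IUPAC_SETS[[p]]
      }
    }
  }
  m
}

scan_strand <- function(tchars, pattern_chars, anchor_positions, max_mismatch,
                        match_mat) {
  L <- length(pattern_chars)
  n <- length(tchars)
  if (n < L) return(list(start = integer(), mismatches = integer()))
  npos <- n - L + 1L
  mm <- integer(npos)
  anchor_bad <- logical(npos)
  for (j in seq_len(L)) {
    hit <- match_mat[pattern_chars[[j]], tchars[j:(j + npos - 1L)]]
    if (j %in% anchor_positions) {
      anchor_bad <- anchor_bad | !hit
    } else {
      mm <- mm + !hit
    }
  }
  keep <- which(!anchor_bad & mm <= max_mismatch)
  list(start = unname(keep - 1L), mismatches = unname(mm[keep]))
}

#' Find degenerate-primer binding sites on a template
#'
#' Scans both strands of a template for matches of an IUPAC-degenerate
#' primer. A degenerate symbol matches any base in its set. Template
#' `N`s match nothing by default (conservative for assay specificity);
#' set `permissive_n = TRUE` to resolve primer-vs-N by set
#' intersection. The 3'-terminal `anchor3` bases of the primer must
#' match exactly (polymerase extension requires a matched 3' end);
#' `max_mismatch` applies only outside the anchor.
#'
#' @param template DNA string (A/C/G/T/N).
#' @param primer Primer name or IUPAC sequence.
#' @param max_mismatch Mismatches tolerated outside the 3' anchor
#'   (default 0).
#' @param anchor3 Length of the exact-match 3' anchor (default 3).
#' @param permissive_n Treat template `N` as intersecting (default
#'   `FALSE`).
#' @param template_id Identifier recorded in the output (default
#'   `"template"`).
#' @return Tibble of sites sorted by coordinate: `template_id`,
#'   `start`, `end` (0-based half-open on the + strand), `strand`
#'   (`"+"`/`"-"`), `mismatches` (count outside the anchor). A template
#'   shorter than the primer yields an empty result, not an error.
#' @export
find_binding_sites <- function(template, primer, max_mismatch = 0L,
                               anchor3 = 3L, permissive_n = FALSE,
                               template_id = "template") {
  pseq <- get_primer(primer)
  pchars <- check_primer_seq(pseq)
  L <- length(pchars)
  tchars <- strsplit(toupper(template), "")[[1L]]
  bad <- which(!tchars %in% c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop("template contains non-A/C/G/T/N symbol ",
         dQuote(tchars[[bad[[1L]]]]), " at position ", bad[[1L]],
         call. = FALSE)
  }
  mm_mat <- iupac_match_matrix(permissive_n)
  anchor3 <- min(anchor3, L)
  # + strand: primer read 5'->3' along template; 3' anchor = last bases
  plus <- scan_strand(tchars, pchars, anchor_positions = (L - anchor3 + 1L):L,
                      max_mismatch = max_mismatch, match_mat = mm_mat)
  # - strand: template contains revcomp(primer); primer 3' end maps to the
  # first positions of the reverse-complemented pattern
  rc_chars <- strsplit(revcomp(pseq), "")[[1L]]
  minus <- scan_strand(tchars, rc_chars, anchor_positions = seq_len(anchor3),
                       max_mismatch = max_mismatch, match_mat = mm_mat)
  out <- tibble(
    template_id = template_id,
    start = c(plus$start, minus$start),
    end = c(plus$start, minus$start) + L,
    strand = rep(c("+", "-"), c(length(plus$start), length(minus$start))),
    mismatches = c(plus$mismatches, minus$mismatches)
  )
  arrange(out, .data$start, .data$strand)
}

as_template_tbl <- function(templates) {
  if (is.data.frame(templates)) {
    if (!all(c("label", "sequence") %in% names(templates))) {
      stop("template tibble needs columns label, sequence", call. = FALSE)
    }
    tibble(label = as.character(templates$label),
           sequence = as.character(templates$sequence))
  } else if (is.character(templates)) {
    lab <- names(templates) %||% paste0("template", seq_along(templates))
    tibble(label = lab, sequence = unname(templates))
  } else {
    stop("templates must be a tibble(label, sequence) or a named character ",
         "vector", call. = FALSE)
  }
}

gc_fraction <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  acgt <- chars[chars %in% c("A", "C", "G", "T")]
  if (!length(acgt)) return(NA_real_)
  mean(acgt %in% c("G", "C"))
}

#' Predict PCR amplicons for a degenerate primer pair
#'
#' Pairs every + strand forward-primer site with every downstream
#' - strand reverse-primer site within the length limit. Product length
#' follows the standard PCR convention: it includes both primer
#' footprints. Coordinates are 0-based half-open internally (1-based
#' inclusive only in rendered reports).
#'
#' @param templates Tibble (`label`, `sequence`) or named character
#'   vector of templates.
#' @param fwd,rev Primer names or IUPAC sequences.
#' @param max_mismatch,anchor3,permissive_n See [find_binding_sites()].
#' @param max_length Maximum product length in bp (default 2000).
#' @return A tibble sorted by template, start, then length:
#'   `template_id`, `start`, `end`, `length`, `sequence` (full
#'   product), `core` (inter-primer subsequence), `gc_fraction`.
#'   Templates without product contribute no rows.
#' @export
predict_amplicons <- function(templates, fwd, rev, max_mismatch = 0L,
                              anchor3 = 3L, permissive_n = FALSE,
                              max_length = 2000L) {
  tt <- as_template_tbl(templates)
  fseq <- get_primer(fwd)
  rseq <- get_primer(rev)
  lf <- nchar(fseq)
  lr <- nchar(rseq)
  one <- function(label, template) {
    fh <- find_binding_sites(template, fseq, max_mismatch, anchor3,
                             permissive_n, template_id = label)
    fh <- fh[fh$strand == "+", ]
    rh <- find_binding_sites(template, rseq, max_mismatch, anchor3,
                             permissive_n, template_id = label)
    rh <- rh[rh$strand == "-", ]
    if (!nrow(fh) || !nrow(rh)) return(NULL)
    combos <- tidyr::expand_grid(fi = seq_len(nrow(fh)), ri = seq_len(nrow(rh)))
    combos <- combos |>
      mutate(fstart = fh$start[.data$fi], fend = fh$end[.data$fi],
             rstart = rh$start[.data$ri], rend = rh$end[.data$ri],
             length = .data$rend - .data$fstart) |>
      filter(.data$rstart >= .data$fend, .data$length <= max_length)
    if (!nrow(combos)) return(NULL)
    tibble(
      template_id = label,
      start = combos$fstart,
      end = combos$rend,
      length = combos$length,
      sequence = substr(rep(template, nrow(combos)),
                        combos$fstart + 1L, combos$rend),
      core = substr(rep(template, nrow(combos)),
                    combos$fstart + lf + 1L, combos$rstart)
    )
  }
  out <- bind_rows(purrr::map2(tt$label, tt$sequence, one))
  if (!nrow(out)) {
    return(tibble(template_id = character(), start = integer(),
                  end = integer(), length = integer(), sequence = character(),
                  core = character(), gc_fraction = numeric()))
  }
  out |>
    mutate(gc_fraction = vapply(.data$sequence, gc_fraction, numeric(1L),
                                USE.NAMES = FALSE)) |>
    arrange(match(.data$template_id, tt$label), .data$start, .data$length)
}

#' Multiplex amplification matrix
#'
#' Predicts, for every template and primer pair, the lengths of all
#' products — the in-silico analogue of running a multiplex reaction
#' and asking which pair amplifies which species. Off-target products
#' are reported, not hidden: a template amplified by more than one pair
#' surfaces as multiple lengths in its row.
#'
#' @param templates Tibble (`label`, `sequence`) or named character
#'   vector; labels must be unique.
#' @param pairs Named list of `c(fwd, rev)` primer-name pairs, e.g.
#'   `list(p16S = c("16S-Ac-F1", "WORM-16S-R1"))`.
#' @inheritParams predict_amplicons
#' @return Tibble with one row per template x pair: `template_id`,
#'   `pair`, `n_products`, `lengths` (list column), `lengths_txt`
#'   (comma-separated, `""` when empty) — directly serializable as TSV.
#' @export
multiplex_predict <- function(templates, pairs, max_mismatch = 0L,
                              anchor3 = 3L, permissive_n = FALSE,
                              max_length = 2000L) {
  tt <- as_template_tbl(templates)
  if (anyDuplicated(tt$label)) {
    stop("duplicate template labels: ",
         paste(unique(tt$label[duplicated(tt$label)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(names(pairs))) {
    names(pairs) <- vapply(pairs, paste, character(1L), collapse = "x")
  }
  rows <- purrr::imap(pairs, function(pr, pname) {
    amps <- predict_amplicons(tt, pr[[1L]], pr[[2L]], max_mismatch, anchor3,
                              permissive_n, max_length)
    lens <- lapply(tt$label, function(l) amps$length[amps$template_id == l])
    tibble(template_id = tt$label, pair = pname, lengths = lens)
  })
  bind_rows(rows) |>
    mutate(
      n_products = vapply(.data$lengths, length, integer(1L)),
      lengths_txt = vapply(.data$lengths, paste, character(1L), collapse = ",")
    ) |>
    arrange(match(.data$template_id, tt$label), match(.data$pair, names(pairs)))
}
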