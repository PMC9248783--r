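#' Extract the primer-amplified subregion from COI sequences
#'
#' Runs in-silico PCR on each sequence and returns the amplified
#' subregion: by default the inter-primer *core* (primer footprints
#' excluded, since in a real amplicon any template variation under the
#' primers is overwritten by the primers themselves), or the full
#' product with `mode = "full"`. Sequences yielding zero or multiple
#' products are recorded as per-sequence failures and the run
#' continues; only an all-failed input is an error. No multiple
#' sequence alignment is performed — primer anchoring plus equal-length
#' enforcement downstream replaces it for this subregion.
#'
#' @param seqs Tibble (`label`, `sequence`) or named character vector.
#' @param fwd,rev Primer names or IUPAC sequences (defaults: the
#'   EW_COI_F2 / EW_COI_R1 pair).
#' @param mode `"core"` (default) or `"full"`.
#' @param max_mismatch Mismatches tolerated outside the 3' anchor
#'   (default 0); relaxations are recorded in the result attributes.
#' @return Tibble `label`, `subregion` (`NA` on failure), `status`
#'   (`"ok"`/`"failed"`), `note`.
#' @export
extract_subregion <- function(seqs, fwd = "EW_COI_F2", rev = "EW_COI_R1",
                              mode = c("core", "full"), max_mismatch = 0L) {
  mode <- match.arg(mode)
  tt <- as_template_tbl(seqs)
  one <- function(label, sequence) {
    amps <- predict_amplicons(tibble(label = label, sequence = sequence),
                              fwd, rev, max_mismatch = max_mismatch)
    if (nrow(amps) == 0L) {
      tibble(label = label, subregion = NA_character_, status = "failed",
             note = "no amplicon")
    } else if (nrow(amps) > 1L) {
      tibble(label = label, subregion = NA_character_, status = "failed",
             note = paste0(nrow(amps), " amplicons"))
    } else {
      tibble(label = label,
             subregion = if (mode == "core") amps$core else amps$sequence,
             status = "ok", note = "")
    }
  }
  out <- bind_rows(purrr::map2(tt$label, tt$sequence, one))
  if (all(out$status == "failed")) {
    stop("no sequence yielded a single amplicon with this primer pair",
         call. = FALSE)
  }
  attr(out, "mode") <- mode
  attr(out, "max_mismatch") <- max_mismatch
  out
}

#' Collapse equal-length sequences into haplotypes
#'
#' Exact-identity collapse, case-insensitive. Haplotype ids `h1`,
#' `h2`, ... follow first occurrence in the input, so permuting the
#' input relabels but never re-partitions. Sequences must share one
#' length: with primer-anchored extraction a length difference means a
#' failed or indel-bearing core, which is reported as an error rather
#' than aligned away.
#'
#' @param seqs Tibble (`label`, `sequence`), a tibble from
#'   [extract_subregion()] (failed rows dropped with a message), or a
#'   named character vector.
#' @return An `hrm_haplotypes` tibble: `haplotype`, `sequence`
#'   (uppercase), `n`, `members` (list of labels).
#' @export
#' @examples
#' collapse_haplotypes(c(a = "AAA", b = "AAA", c = "AAT"))
collapse_haplotypes <- function(seqs) {
  if (is.data.frame(seqs) && "subregion" %in% names(seqs)) {
    failed <- seqs$status == "failed"
    if (any(failed)) {
      message("dropping ", sum(failed), " failed extraction(s): ",
              paste(seqs$label[failed], collapse = ", "))
    }
    seqs <- tibble(label = seqs$label[!failed],
                   sequence = seqs$subregion[!failed])
  }
  tt <- as_template_tbl(seqs)
  if (!nrow(tt)) stop("no sequences to collapse", call. = FALSE)
  sq <- toupper(tt$sequence)
  lens <- nchar(sq)
  if (length(unique(lens)) > 1L) {
    off <- tt$label[lens != median(lens)]
    stop("sequences of mixed length; offenders: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  uniq <- unique(sq)  # first-occurrence order
  out <- tibble(
    haplotype = paste0("h", seq_along(uniq)),
    sequence = uniq,
    n = vapply(uniq, function(u) sum(sq == u), integer(1L),
               USE.NAMES = FALSE),
    members = lapply(uniq, function(u) tt$label[sq == u])
  )
  class(out) <- c("hrm_haplotypes", class(out))
  out
}

#' Pairwise p-distance matrix
#'
#' Proportion of differing positions between equal-length sequences.
#' Positions where either sequence carries an ambiguous base (anything
#' outside A/C/G/T, e.g. `N`) are excluded from both numerator and
#' denominator. A pair with zero comparable positions is `NA`
#' (flagged missing, never reported as 0).
#'
#' @param seqs Tibble (`label`, `sequence`), an `hrm_haplotypes` table
#'   (rows keyed by haplotype id), or a named character vector.
#' @return Symmetric numeric matrix in `[0, 1]` with zero diagonal.
#' @export
#' @examples
#' p_distance_matrix(c(x = "AAAA", y = "AATT"))["x", "y"]  # 0.5
p_distance_matrix <- function(seqs) {
  if (inherits(seqs, "hrm_haplotypes")) {
    seqs <- setNames(seqs$sequence, seqs$haplotype)
  }
  tt <- as_template_tbl(seqs)
  sq <- toupper(tt$sequence)
  if (length(unique(nchar(sq))) > 1L) {
    stop("sequences must have equal length", call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(sq, ""))
  known <- matrix(chars %in% c("A", "C", "G", "T"), nrow = nrow(chars))
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(tt$label, tt$label))
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      if (i == j) next
      comp <- known[i, ] & known[j, ]
      d[i, j] <- d[j, i] <- if (!any(comp)) {
        NA_real_
      } else {
        mean(chars[i, comp] != chars[j, comp])
      }
    }
  }
  if (anyNA(d)) {
    warning("pair(s) with zero comparable positions flagged as NA",
            call. = FALSE)
  }
  d
}

#' UPGMA tree from a distance matrix
#'
#' Standard unweighted pair-group agglomeration (average linkage over
#' cluster sizes) yielding an ultrametric tree: all root-to-leaf path
#' lengths are equal, and a pair at distance `d` joins at height
#' `d / 2` on each side. Labels are sorted lexicographically before
#' agglomeration so distance ties resolve toward the smallest leaf
#' label, making the construction deterministic.
#'
#' @param d Symmetric nonnegative matrix with zero diagonal (or a
#'   `dist`).
#' @return An [ape::as.phylo()] tree (class `phylo`) with branch
#'   lengths; serialize with [ape::write.tree()].
#' @export
#' @examples
#' d <- matrix(c(0, .1, .4, .1, 0, .4, .4, .4, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' ape::write.tree(upgma_tree(d))  # (C:0.2,(A:0.05,B:0.05):0.15);
upgma_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("d must be a square matrix or dist", call. = FALSE)
  }
  if (anyNA(d)) stop("distance matrix contains NA", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(d < 0) || any(abs(diag(d)) > 1e-12)) {
    stop("distances must be nonnegative with zero diagonal", call. = FALSE)
  }
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- hclust(as.dist(d), method = "average")
  tree <- ape::as.phylo(hc)
  attr(tree, "method") <- "UPGMA"
  tree
}

#' Concordance between melt groups and sequence haplotypes
#'
#' Cross-tabulates HRM group membership against sequence haplotypes
#' and checks the relationship that makes a melt assay a usable
#' haplotype screen: every haplotype must map into exactly one melt
#' group (groups may merge several haplotypes — melt-neutral variation
#' is invisible by design — but a haplotype split across groups is an
#' inconsistency and is reported by name).
#'
#' @param groups An `hrm_clusters` object or a tibble with
#'   `sample_id`, `group`.
#' @param haplotypes An `hrm_haplotypes` table whose `members` share
#'   ids with `groups`.
#' @return An `hrm_concordance` object: `table` (group x haplotype
#'   counts), `consistent` flag, `violations` (haplotypes spanning
#'   several groups), `mapping` tibble (haplotype -> group, `NA` when
#'   split).
#' @export
concordance <- function(groups, haplotypes) {
  if (inherits(groups, "hrm_clusters")) groups <- tidy(groups)
  stopifnot(all(c("sample_id", "group") %in% names(groups)),
            inherits(haplotypes, "hrm_haplotypes"))
  hap_of <- tibble(
    sample_id = unlist(haplotypes$members),
    haplotype = rep(haplotypes$haplotype,
                    vapply(haplotypes$members, length, integer(1L)))
  )
  shared <- intersect(groups$sample_id, hap_of$sample_id)
  if (!length(shared)) {
    stop("groups and haplotypes share no sample ids", call. = FALSE)
  }
  joined <- inner_join(groups, hap_of, by = "sample_id")
  tab <- table(group = joined$group, haplotype = joined$haplotype)
  tab <- tab[, haplotypes$haplotype[haplotypes$haplotype %in%
                                      colnames(tab)], drop = FALSE]
  per_hap <- joined |>
    group_by(.data$haplotype) |>
    summarise(n_groups = length(unique(.data$group)),
              group = if (length(unique(.data$group)) == 1L)
                unique(.data$group) else NA_integer_,
              .groups = "drop")
  violations <- per_hap$haplotype[per_hap$n_groups > 1L]
  structure(
    list(table = tab, consistent = length(violations) == 0L,
         violations = violations,
         mapping = select(per_hap, "haplotype", "group")),
    class = "hrm_concordance")
}

#' @importFrom dplyr inner_join
#' @method print hrm_concordance
#' @export
print.hrm_concordance <- function(x, ...) {
  cat("<hrm_concordance> ", if (x$consistent) "consistent" else
    paste0("INCONSISTENT (split haplotypes: ",
           paste(x$violations, collapse = ", "), ")"), "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @method tidy hrm_concordance
#' @export
tidy.hrm_concordance <- function(x, ...) x$mapping

#' @method glance hrm_concordance
#' @export
glance.hrm_concordance <- function(x, ...) {
  tibble(n_groups = nrow(x$table), n_haplotypes = ncol(x$table),
         consistent = x$consistent, n_violations = length(x$violations))
}
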