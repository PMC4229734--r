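# Expression normalization scales and specificity classification.
#
# Es_i  = abundance_i / sum_i(abundance_i)   (per gene; values sum to 1)
# pmax_i = 100 * abundance_i / abundance_max (per gene; max condition = 100)
#
# Missing cells (unreliable measurements) contribute 0 to Es totals and are
# excluded from the pmax maximum.

validate_expression <- function(expr) {
  stopifnot(is.data.frame(expr), ncol(expr) >= 2)
  if (names(expr)[1] != "gene") {
    names(expr)[1] <- "gene"
  }
  if (anyDuplicated(expr$gene)) {
    dup <- unique(expr$gene[duplicated(expr$gene)])
    stop_parse("duplicate gene ID(s): %s", toString(head(dup, 5)))
  }
  conds <- names(expr)[-1]
  if (anyDuplicated(conds) || any(!nzchar(conds))) {
    stop_parse("condition labels must be unique and non-empty")
  }
  vals <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop_parse("abundance columns must be numeric")
  if (any(vals < 0, na.rm = TRUE)) {
    bad <- expr$gene[which(rowSums(vals < 0, na.rm = TRUE) > 0)[1]]
    stop_parse("negative abundance for gene %s", bad)
  }
  expr
}

#' Read a gene-by-condition expression table
#'
#' Delimited text with a header of condition labels and gene IDs in the
#' first column. Empty cells and `NA` become missing measurements; duplicate
#' gene rows and negative abundances are rejected.
#'
#' @param path File to read.
#' @param delim Field delimiter (default tab).
#' @return Wide tibble: `gene` column plus one numeric column per condition
#'   (`NA` = missing).
#' @export
read_expression_table <- function(path, delim = "\t") {
  df <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = "c"),
    na = c("", "NA"), progress = FALSE
  )
  if (ncol(df) < 2) stop_parse("expression table %s needs >= 2 columns", path)
  for (j in 2:ncol(df)) {
    v <- df[[j]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      stop_parse(
        "non-numeric abundance '%s' in column %s, row %d",
        v[bad[1]], names(df)[j], bad[1]
      )
    }
    df[[j]] <- num
  }
  validate_expression(df)
}

#' @rdname read_expression_table
#' @param expr Wide expression tibble to write.
#' @export
write_expression_table <- function(expr, path, delim = "\t") {
  readr::write_delim(expr, path, delim = delim, na = "NA", progress = FALSE)
  invisible(path)
}

#' Collapse a replicate table into an expression matrix
#'
#' A gene/condition cell is retained, with the mean of its replicate
#' signals, only when the measurement was called present in *all*
#' replicates; otherwise the cell is missing.
#'
#' @param raw Long tibble with columns `gene`, `condition`, `replicate`,
#'   `signal`, `call` (values `"present"`/`"absent"`).
#' @param n_replicates Expected replicate count per cell.
#' @return Wide expression tibble (`NA` = missing).
#' @export
preprocess_replicates <- function(raw, n_replicates = 4) {
  need <- c("gene", "condition", "replicate", "signal", "call")
  if (!all(need %in% names(raw))) {
    stop_parse("replicate table needs columns: %s", toString(need))
  }
  cell <- raw |>
    group_by(.data$gene, .data$condition) |>
    summarise(
      n_rep = n(),
      all_present = all(.data$call == "present"),
      mean_signal = mean(.data$signal),
      .groups = "drop"
    )
  if (any(cell$n_rep != n_replicates)) {
    bad <- cell[cell$n_rep != n_replicates, ][1, ]
    stop_parse(
      "gene %s / %s has %d replicates, expected %d",
      bad$gene, bad$condition, bad$n_rep, n_replicates
    )
  }
  cell |>
    mutate(value = ifelse(.data$all_present, .data$mean_signal, NA_real_)) |>
    select("gene", "condition", "value") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value") |>
    arrange(.data$gene)
}

expr_long <- function(expr) {
  tidyr::pivot_longer(
    expr,
    cols = -"gene", names_to = "condition", values_to = "abundance"
  )
}

#' Expression specificity (Es) profile
#'
#' For each gene, the abundance in a condition as a fraction of the gene's
#' total abundance over all conditions. Missing cells contribute 0 to the
#' total and get `es = 0`. Genes with zero total abundance get an undefined
#' (`NA`) profile and are listed in the `degenerate_genes` attribute.
#'
#' @param expr Wide expression tibble (`gene` + condition columns).
#' @return Long tibble (`gene`, `condition`, `abundance`, `es`,
#'   `total_abundance`) of class `es_profile`.
#' @examples
#' expr <- tibble::tibble(gene = "g1", a = 2, b = 3, c = 5)
#' compute_specificity(expr)$es
#' @export
compute_specificity <- function(expr) {
  expr <- validate_expression(expr)
  long <- expr_long(expr)
  out <- long |>
    group_by(.data$gene) |>
    mutate(
      total_abundance = sum(.data$abundance, na.rm = TRUE),
      es = ifelse(
        .data$total_abundance > 0,
        dplyr::coalesce(.data$abundance, 0) / .data$total_abundance,
        NA_real_
      )
    ) |>
    ungroup() |>
    select("gene", "condition", "abundance", "es", "total_abundance")
  degenerate <- unique(out$gene[out$total_abundance == 0])
  structure(out,
    degenerate_genes = degenerate,
    class = c("es_profile", class(out))
  )
}

#' Percent-of-maximum (pmax) profile
#'
#' For each gene, the abundance in a condition as a percentage of its
#' abundance in the condition where it is maximal. The maximum is taken
#' over non-missing cells; missing cells get `NA` pmax. Ties for the
#' maximal condition break to the lexicographically first label. All-zero
#' or all-missing genes get an undefined profile and are listed in the
#' `degenerate_genes` attribute.
#'
#' @inheritParams compute_specificity
#' @return Long tibble (`gene`, `condition`, `abundance`, `pmax`,
#'   `max_condition`, `max_abundance`) of class `pmax_profile`.
#' @export
compute_pmax <- function(expr) {
  expr <- validate_expression(expr)
  long <- expr_long(expr) |> arrange(.data$gene, .data$condition)
  out <- long |>
    group_by(.data$gene) |>
    mutate(
      max_abundance = ifelse(
        all(is.na(.data$abundance)), 0, max(.data$abundance, na.rm = TRUE)
      ),
      max_condition = ifelse(
        .data$max_abundance > 0,
        .data$condition[which.max(.data$abundance)],
        NA_character_
      ),
      # divide before scaling so the maximal condition is exactly 100 and
      # no value exceeds 100 by a rounding ulp
      pmax = ifelse(
        .data$max_abundance > 0,
        100 * (.data$abundance / .data$max_abundance),
        NA_real_
      )
    ) |>
    ungroup()
  degenerate <- unique(out$gene[out$max_abundance == 0])
  structure(out,
    degenerate_genes = degenerate,
    class = c("pmax_profile", class(out))
  )
}

#' Classification thresholds for the tissue and stage regimes
#'
#' Tissue regime: specific when Es >= 0.8 in some tissue; ubiquitous when
#' abundance is non-zero in every tissue (floor 0, strict). Stage regime:
#' specific when Es >= 0.19; ubiquitous when Es > 0.005 at every time point.
#'
#' @param regime `"tissue"` or `"stage"`, or supply explicit cutoffs.
#' @param specific_cutoff,ubiquitous_floor Optional overrides.
#' @return A `class_thresholds` list.
#' @export
classification_thresholds <- function(regime = c("tissue", "stage"),
                                      specific_cutoff = NULL,
                                      ubiquitous_floor = NULL) {
  regime <- match.arg(regime)
  cutoff <- specific_cutoff %||% if (regime == "tissue") 0.8 else 0.19
  floor_ <- ubiquitous_floor %||% if (regime == "tissue") 0 else 0.005
  if (!(cutoff > 0 && cutoff <= 1) || !(floor_ >= 0 && floor_ < cutoff)) {
    stop_config(
      "need 0 < specific_cutoff <= 1 and 0 <= ubiquitous_floor < specific_cutoff"
    )
  }
  structure(
    list(
      regime = regime, specific_cutoff = cutoff, ubiquitous_floor = floor_
    ),
    class = "class_thresholds"
  )
}

#' Classify genes into specificity bins
#'
#' Three mutually exclusive bins over genes with data: `specific` (Es at or
#' above the cutoff in some condition; the condition with maximal Es, ties
#' broken lexicographically), else `ubiquitous` (Es strictly above the floor
#' in every condition), else `NUNS` (non-ubiquitous non-specific). Genes
#' with no usable data (zero total abundance) are `unclassified`.
#'
#' @param profile An `es_profile` from [compute_specificity()].
#' @param thresholds A [classification_thresholds()] object, or a regime
#'   name passed to it.
#' @return Tibble (`gene`, `class`, `condition`) where `condition` is the
#'   assigned condition for specific genes and `NA` otherwise.
#' @export
classify_genes <- function(profile, thresholds = "tissue") {
  if (is.character(thresholds)) {
    thresholds <- classification_thresholds(thresholds)
  }
  stopifnot(inherits(thresholds, "class_thresholds"))
  cutoff <- thresholds$specific_cutoff
  floor_ <- thresholds$ubiquitous_floor
  profile |>
    arrange(.data$gene, .data$condition) |>
    group_by(.data$gene) |>
    summarise(
      class = if (all(is.na(.data$es))) {
        "unclassified"
      } else if (max(.data$es) >= cutoff) {
        "specific"
      } else if (all(.data$es > floor_)) {
        "ubiquitous"
      } else {
        "NUNS"
      },
      condition = if (!all(is.na(.data$es)) && max(.data$es) >= cutoff) {
        .data$condition[which.max(.data$es)]
      } else {
        NA_character_
      },
      .groups = "drop"
    )
}
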