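# Synthetic annotation sets with planted context-relevant terms.

#' Annotation set container
#'
#' @param terms Named list mapping term labels to character vectors of genes.
#' @param background Character vector of background genes; every annotated
#'   gene must belong to it.
#' @return An `annotation_set` list.
#' @export
annotation_set <- function(terms, background) {
  stopifnot(is.list(terms), !is.null(names(terms)) || length(terms) == 0)
  terms <- lapply(terms, function(g) sort(unique(as.character(g))))
  stray <- setdiff(unlist(terms), background)
  if (length(stray)) {
    abort(sprintf(
      "%d annotated gene(s) missing from background (e.g. %s)",
      length(stray), toString(head(stray, 3))
    ))
  }
  structure(
    list(terms = terms, background = sort(unique(as.character(background)))),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set: %d terms over %d background genes>\n",
    length(x$terms), length(x$background)
  ))
  invisible(x)
}

#' Simulate an annotation set with planted context-relevant terms
#'
#' Generates `n_terms` annotation terms over the simulated gene universe.
#' A fraction of terms is planted on conditions: a planted term's gene set
#' oversamples genes specific to its condition by `planted_term_fold`
#' (weighted sampling without replacement); the remaining background terms
#' draw genes uniformly.
#'
#' @inheritParams simulate_ppi_network
#' @param n_planted Number of planted terms (default: 20% of `n_terms`,
#'   at least 3, at most one per condition present in the truth).
#' @return A list with `annotations` (an [annotation_set()]) and `planted`
#'   (tibble `term`, `condition`).
#' @export
simulate_annotations <- function(truth, config, n_planted = NULL) {
  validate_sim_config(config)
  genes <- truth$gene
  conditions <- sort(unique(truth$condition[!is.na(truth$condition)]))
  n_planted <- n_planted %||% min(
    length(conditions), max(3L, round(config$n_terms * 0.2))
  )
  with_seed(child_seed(config$seed, 401), {
    planted_conditions <- if (n_planted > 0 && length(conditions)) {
      sample(conditions, n_planted)
    } else {
      character(0)
    }
    sizes <- sample(
      seq(config$term_size[1], config$term_size[2]),
      config$n_terms,
      replace = TRUE
    )
    sizes <- pmin(sizes, length(genes))
    terms <- vector("list", config$n_terms)
    names(terms) <- sprintf("term_%03d", seq_len(config$n_terms))
    for (k in seq_len(config$n_terms)) {
      if (k <= length(planted_conditions)) {
        w <- rep(1, length(genes))
        hit <- truth$class == "specific" & !is.na(truth$condition) &
          truth$condition == planted_conditions[k]
        w[hit] <- config$planted_term_fold
        terms[[k]] <- sample(genes, sizes[k], prob = w)
      } else {
        terms[[k]] <- sample(genes, sizes[k])
      }
    }
    planted <- tibble(
      term = names(terms)[seq_along(planted_conditions)],
      condition = planted_conditions
    )
    list(annotations = annotation_set(terms, genes), planted = planted)
  })
}

#' Read / write GMT annotation files
#'
#' GMT: one term per line, `term<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file.
#' @param background Background gene set; defaults to the union of all
#'   annotated genes.
#' @return An [annotation_set()].
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    stop_parse("GMT line %d has fewer than 3 fields", bad[1])
  }
  terms <- lapply(parts, function(p) p[-(1:2)])
  names(terms) <- vapply(parts, `[[`, character(1), 1)
  annotation_set(terms, background %||% unique(unlist(terms)))
}

#' @rdname read_gmt
#' @param annotations An [annotation_set()] to write.
#' @export
write_gmt <- function(annotations, path) {
  lines <- vapply(names(annotations$terms), function(tm) {
    paste(c(tm, "na", annotations$terms[[tm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
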