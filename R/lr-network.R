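#' Merge ligand-receptor pair tables into one database
#'
#' Union of one or more pair tables (e.g. exports of CellTalkDB,
#' CellPhoneDB and CellChat pair lists), deduplicated on the
#' case-normalized (ligand, receptor) pair with source tags concatenated,
#' in deterministic (ligand, receptor) lexicographic order. Gene symbols
#' are normalized to Title-case (mouse convention). Malformed rows
#' (missing ligand or receptor) are rejected with a row-level report
#' attached as `attr(, "rejected")`.
#'
#' @param ... Data frames with columns `ligand` and `receptor` (optional
#'   `source`).
#' @return Tibble (class `lr_database`): ligand, receptor, source.
#' @export
#' @examples
#' merge_lr_databases(tibble::tibble(ligand = "S100a6", receptor = "Anxa2"))
merge_lr_databases <- function(...) {
  tables <- list(...)
  if (length(tables) == 1L && is.list(tables[[1]]) && !is.data.frame(tables[[1]])) {
    tables <- tables[[1]]
  }
  if (length(tables) == 0L || all(map_dbl(tables, nrow) == 0)) {
    warn("no pairs supplied; returning an empty database")
  }
  norm_symbol <- function(x) {
    x <- tolower(trimws(as.character(x)))
    paste0(toupper(substring(x, 1, 1)), substring(x, 2))
  }
  tagged <- imap(tables, function(tb, i) {
    tb <- as_tibble(tb)
    if (!all(c("ligand", "receptor") %in% names(tb))) {
      abort(sprintf("table %s lacks ligand/receptor columns", i))
    }
    if (!"source" %in% names(tb)) tb$source <- paste0("table", i)
    tb[, c("ligand", "receptor", "source")]
  })
  all_rows <- bind_rows(tagged)
  bad <- filter(all_rows, is.na(.data$ligand) | is.na(.data$receptor) |
                  !nzchar(.data$ligand) | !nzchar(.data$receptor))
  ok <- anti_join(all_rows, bad, by = names(all_rows)) |>
    mutate(ligand = norm_symbol(.data$ligand), receptor = norm_symbol(.data$receptor)) |>
    group_by(.data$ligand, .data$receptor) |>
    summarise(source = paste(sort(unique(.data$source)), collapse = ";"), .groups = "drop") |>
    arrange(.data$ligand, .data$receptor)
  if (nrow(bad)) warn(sprintf("%d malformed row(s) rejected", nrow(bad)))
  attr(ok, "rejected") <- bad
  class(ok) <- c("lr_database", class(ok))
  ok
}

#' Per-cluster gene detection fractions
#'
#' Fraction of a cluster's cells in which each gene is detected
#' (count > 0), the quantity thresholded by the interaction-calling rule.
#' Returned in long form. Threshold comparisons downstream are done in
#' exact rational arithmetic so a gene detected in exactly half the cells
#' passes an "at least 50 percent" rule.
#'
#' @param mat Count or log1p-normalized matrix, genes x cells (detection
#'   is identical on either).
#' @param clusters Named character vector or tibble (cell, cluster).
#' @param genes Optional gene subset (default all).
#' @return Tibble: cluster, gene, n_detected, n_cells, fraction.
#' @export
expression_fractions <- function(mat, clusters, genes = rownames(mat)) {
  assert_counts(mat, "mat")
  clusters <- as_cluster_vector(clusters, colnames(mat))
  genes <- intersect(genes, rownames(mat))
  m <- mat[genes, , drop = FALSE]
  out <- map(unique(clusters), function(cl) {
    cols <- clusters == cl
    if (!any(cols)) abort(sprintf("empty cluster '%s'", cl))
    nd <- Matrix::rowSums(m[, cols, drop = FALSE] > 0)
    tibble(cluster = cl, gene = genes, n_detected = as.integer(nd),
           n_cells = sum(cols), fraction = as.numeric(nd) / sum(cols))
  })
  bind_rows(out)
}

#' Call ligand-receptor interaction edges in one condition
#'
#' For every ordered (sender, receiver) cluster pair — self-pairs
#' included — an edge is emitted for each database pair whose ligand is
#' detected in at least `min_fraction` of the sender cluster's cells and
#' whose receptor is detected in at least `min_fraction` of the receiver
#' cluster's cells (both thresholds inclusive, compared in exact rational
#' arithmetic). Raising `min_fraction` can only remove edges.
#'
#' @param fractions Output of [expression_fractions()] for one condition.
#' @param db An [merge_lr_databases()] database (or tibble with ligand,
#'   receptor columns).
#' @param condition Label stored on the edges.
#' @param min_fraction Detection threshold (default 0.5).
#' @return Tibble (class `lr_edges`): sender, receiver, ligand, receptor,
#'   condition, ligand_fraction, receptor_fraction.
#' @export
call_interactions <- function(fractions, db, condition, min_fraction = 0.5) {
  if (!all(c("ligand", "receptor") %in% names(db))) abort("db needs ligand/receptor columns")
  lig <- fractions |>
    inner_join(distinct(db, .data$ligand), by = c(gene = "ligand")) |>
    filter(frac_at_least(.data$n_detected, .data$n_cells, min_fraction)) |>
    select(sender = "cluster", ligand = "gene", ligand_fraction = "fraction")
  rec <- fractions |>
    inner_join(distinct(db, .data$receptor), by = c(gene = "receptor")) |>
    filter(frac_at_least(.data$n_detected, .data$n_cells, min_fraction)) |>
    select(receiver = "cluster", receptor = "gene", receptor_fraction = "fraction")
  edges <- db |>
    select("ligand", "receptor") |>
    inner_join(lig, by = "ligand", relationship = "many-to-many") |>
    inner_join(rec, by = "receptor", relationship = "many-to-many") |>
    mutate(condition = condition) |>
    select("sender", "receiver", "ligand", "receptor", "condition",
           "ligand_fraction", "receptor_fraction") |>
    arrange(.data$sender, .data$receiver, .data$ligand, .data$receptor)
  attr(edges, "min_fraction") <- min_fraction
  class(edges) <- c("lr_edges", class(edges))
  edges
}

#' Differential interaction network between two conditions
#'
#' Keys every edge by (sender, receiver, ligand, receptor) and labels it
#' `shared` (present in both conditions), `gained` (condition B only) or
#' `lost` (condition A only), with a per-cluster-pair summary. The edge
#' sets must come from the same database and cluster universe.
#'
#' @param edges_a,edges_b [call_interactions()] results for conditions A
#'   (reference, e.g. wild-type) and B (e.g. tumor-bearing).
#' @return List (class `lr_diff`): `edges` (tibble with `status`),
#'   `summary` (per sender/receiver counts of gained/lost/shared),
#'   `conditions`.
#' @export
differential_network <- function(edges_a, edges_b) {
  key <- c("sender", "receiver", "ligand", "receptor")
  if (!all(key %in% names(edges_a)) || !all(key %in% names(edges_b))) {
    abort("edge tables must carry sender/receiver/ligand/receptor")
  }
  cond_a <- unique(edges_a$condition) %||% "A"
  cond_b <- unique(edges_b$condition) %||% "B"
  a <- mutate(edges_a[, key], in_a = TRUE)
  b <- mutate(edges_b[, key], in_b = TRUE)
  edges <- dplyr::full_join(a, b, by = key) |>
    mutate(
      in_a = !is.na(.data$in_a), in_b = !is.na(.data$in_b),
      status = dplyr::case_when(
        .data$in_a & .data$in_b ~ "shared",
        .data$in_b ~ "gained",
        .default = "lost"
      )
    ) |>
    select(-"in_a", -"in_b") |>
    arrange(.data$status, .data$sender, .data$receiver, .data$ligand, .data$receptor)
  summary <- edges |>
    group_by(.data$sender, .data$receiver) |>
    summarise(
      gained = sum(.data$status == "gained"),
      lost = sum(.data$status == "lost"),
      shared = sum(.data$status == "shared"),
      .groups = "drop"
    )
  structure(list(edges = edges, summary = summary,
                 conditions = c(a = cond_a[1], b = cond_b[1])),
            class = "lr_diff")
}

#' @export
print.lr_diff <- function(x, ...) {
  cat(sprintf("<lr_diff> %s vs %s: %d gained, %d lost, %d shared\n",
              x$conditions["b"], x$conditions["a"],
              sum(x$edges$status == "gained"), sum(x$edges$status == "lost"),
              sum(x$edges$status == "shared")))
  invisible(x)
}
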