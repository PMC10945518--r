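#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an enrichment run
#'
#' @param x a `nuc_enrichment_run`.
#' @param ... unused.
#' @return the ranked enrichment table as a plain tibble.
#' @export
tidy.nuc_enrichment_run <- function(x, ...) as_tibble(x$table)

#' @rdname tidy.nuc_enrichment_run
#' @return `glance()`: one-row tibble of run-level metrics and sizes.
#' @export
glance.nuc_enrichment_run <- function(x, ...) {
  base <- tibble(mode = x$params$mode, cell_line = x$cell_line,
                 n_tf = nrow(x$table), n_ranked = sum(!is.na(x$table$rank)),
                 n_dyads = nrow(x$dyads),
                 nr_bp = sum(x$nr$end - x$nr$start),
                 ndr_bp = sum(x$ndr$end - x$ndr$start))
  if (!is.null(x$metrics)) bind_cols(base, x$metrics[c("roc_auc", "pr_auc",
                                                       "max_mcc", "mw_p")])
  else base
}

#' Tidy a profiles run
#'
#' @param x a `nuc_profiles_run`.
#' @param ... unused.
#' @return per-TF summary tibble (occupancy correlation, end/dyad ratio,
#'   cluster assignment when clustering ran).
#' @export
tidy.nuc_profiles_run <- function(x, ...) {
  out <- as_tibble(x$summary)
  if (!is.null(x$clusters)) {
    asg <- x$clusters$assignments[c("tf_name", "cluster", "silhouette", "outlier")]
    out <- left_join(out, asg, by = "tf_name")
  }
  out
}

#' @rdname tidy.nuc_profiles_run
#' @export
glance.nuc_profiles_run <- function(x, ...) {
  tibble(cell_line = x$cell_line, n_tf = nrow(x$summary),
         n_positive_binder = sum(x$summary$positive_binder, na.rm = TRUE),
         median_pcc = stats::median(x$summary$pcc, na.rm = TRUE),
         frac_negative_pcc = mean(x$summary$pcc < 0, na.rm = TRUE),
         n_clustered = if (is.null(x$clusters)) NA_integer_ else
           sum(!is.na(x$clusters$assignments$cluster)),
         n_outliers = if (is.null(x$clusters)) NA_integer_ else
           sum(x$clusters$assignments$outlier))
}

#' Tidy a clustering result
#'
#' @param x a `nuc_clusters`.
#' @param ... unused.
#' @return assignment tibble (keys, cluster, silhouette, outlier).
#' @export
tidy.nuc_clusters <- function(x, ...) as_tibble(x$assignments)

#' @rdname tidy.nuc_clusters
#' @export
glance.nuc_clusters <- function(x, ...) {
  tibble(k = x$params$k, n = nrow(x$assignments),
         n_outliers = sum(x$assignments$outlier),
         n_rejected = nrow(x$rejected),
         mean_silhouette = mean(x$assignments$silhouette, na.rm = TRUE))
}
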