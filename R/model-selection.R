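# Sweep the input number of clusters q, assemble the criteria table, apply
# the one-standard-error rule, and flag spurious solutions.

#' One-standard-error rule
#'
#' Finds `q_best = argmin(values)` (ties toward the smallest q) and returns
#' the smallest q whose value is no more than one standard error of the best
#' model above the best value. The rule only moves toward parsimony:
#' `selected <= q_best`.
#'
#' @param values criterion values, one per q.
#' @param ses non-negative standard errors matching `values`.
#' @param qs the q values (defaults to `seq_along(values)`); must be sorted.
#' @return A list with `q_best` and `q_selected`.
#' @export
one_se_rule <- function(values, ses, qs = seq_along(values)) {
  stopifnot(length(values) >= 1, length(ses) == length(values),
            length(qs) == length(values), !is.unsorted(qs),
            all(ses >= 0, na.rm = TRUE))
  ok <- is.finite(values)
  if (!any(ok)) return(list(q_best = NA_integer_, q_selected = NA_integer_))
  ib <- which(ok)[which.min(values[ok])]
  cutoff <- values[ib] + ses[ib]
  is_ <- which(ok & values <= cutoff)[1L]
  list(q_best = qs[ib], q_selected = qs[is_])
}

#' Sweep q and assemble model-selection criteria
#'
#' Runs [run_em()] for each q in `[q_min, q_max]` (Bethe-minimizing
#' restarts), computes all cross-validation errors and the Bethe free
#' energy, and applies the one-standard-error rule per criterion. The q = 1
#' row uses the closed-form baseline (all four errors coincide there).
#' Engine failures are recorded per q and the sweep continues.
#'
#' @param network an `sbm_network`.
#' @param q_min,q_max sweep range, `1 <= q_min <= q_max`.
#' @param opts engine options passed to [run_em()]; per-q seeds are derived
#'   from `opts$seed`.
#' @return An object of class `selection_result`: `table` (one [cv_report()]
#'   row per q), `results` (the `em_result`s), `selection` (per-criterion
#'   `q_best` / `q_selected`), `flags` (see [diagnostics_report()]), and
#'   `criterion_ordering` (the soft training >= Bayes >= Gibbs check on
#'   selected q).
#' @export
sweep_q <- function(network, q_min, q_max, opts = list()) {
  stopifnot(q_min >= 1, q_min <= q_max)
  o <- default_em_opts(opts)
  qs <- seq.int(q_min, q_max)
  results <- vector("list", length(qs))
  rows <- vector("list", length(qs))
  errors <- character(length(qs))
  for (k in seq_along(qs)) {
    oq <- o
    oq$seed <- (as.integer(o$seed) + 7919L * qs[k]) %% 2147483647L
    res <- tryCatch(run_em(network, qs[k], oq), error = function(e) e)
    if (inherits(res, "error")) {
      errors[k] <- conditionMessage(res)
      rows[[k]] <- NULL
      next
    }
    results[[k]] <- res
    rows[[k]] <- cv_report(network, res)
  }
  tab <- do.call(rbind, rows)
  sel <- lapply(
    c(e_bayes = "e_bayes", e_gibbs = "e_gibbs", e_map = "e_map",
      e_training = "e_training", f_bethe = "f_bethe"),
    function(col) {
      se_col <- switch(col, e_bayes = "se_bayes", e_gibbs = "se_gibbs",
                       e_map = "se_map", e_training = "se_training",
                       f_bethe = "se_f_bethe")
      one_se_rule(tab[[col]], tab[[se_col]], tab$q)
    })
  out <- structure(
    list(table = tab, results = results, qs = qs, selection = sel,
         engine_errors = errors, flags = NULL, criterion_ordering = NULL),
    class = "selection_result")
  out$flags <- diagnostics_report(out)
  ord <- c(training = sel$e_training$q_selected,
           bayes = sel$e_bayes$q_selected,
           gibbs = sel$e_gibbs$q_selected)
  out$criterion_ordering <- list(
    q_selected = ord,
    monotone = !is.unsorted(rev(ord), na.rm = TRUE))
  out
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result over q =", paste(range(x$qs), collapse = ".."), "\n")
  print(x$table, row.names = FALSE)
  for (nm in names(x$selection))
    cat(sprintf("  %-10s q_best = %s, selected = %s\n", nm,
                x$selection[[nm]]$q_best, x$selection[[nm]]$q_selected))
  if (length(x$flags$messages))
    cat("flags:\n", paste0("  ", x$flags$messages, collapse = "\n"), "\n")
  invisible(x)
}

#' Diagnostics for discarding spurious solutions
#'
#' Flags per-q warnings that suggest a "wrong solution": (i) slow BP
#' convergence (median sweep count above `k` times the median over smaller
#' q); (ii) fewer populated clusters than q (the actual number of clusters
#' stops increasing); (iii) non-convergence; (iv) a criterion still
#' decreasing at `q_max` (no saturation — the selected value is then q_max
#' with an explicit flag rather than a confident choice).
#'
#' @param result a `selection_result`.
#' @param k slow-convergence multiplier (default 3).
#' @return A list with `slow_convergence`, `underpopulated`, `not_converged`
#'   (logical vectors over the sweep), `no_saturation` (per criterion), and
#'   human-readable `messages`.
#' @export
diagnostics_report <- function(result, k = 3) {
  tab <- result$table
  msgs <- character(0)
  if (is.null(tab) || nrow(tab) == 0L)
    return(list(slow_convergence = logical(0), underpopulated = logical(0),
                not_converged = logical(0), no_saturation = logical(0),
                messages = "no successful fits"))
  slow <- rep(FALSE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    prior <- tab$bp_iter_median[seq_len(i - 1L)]
    prior <- prior[prior > 0]          # q = 1 is closed-form (0 sweeps)
    if (length(prior) && tab$bp_iter_median[i] > k * stats::median(prior))
      slow[i] <- TRUE
  }
  under <- tab$n_effective < tab$q
  noconv <- !tab$converged
  nosat <- vapply(result$selection, function(s)
    isTRUE(s$q_best == max(tab$q)), logical(1))
  for (i in which(slow))
    msgs <- c(msgs, sprintf("q = %d: slow BP convergence (median %g sweeps)",
                            tab$q[i], tab$bp_iter_median[i]))
  for (i in which(under))
    msgs <- c(msgs, sprintf("q = %d: effective clusters = %d",
                            tab$q[i], tab$n_effective[i]))
  for (i in which(noconv))
    msgs <- c(msgs, sprintf("q = %d: not converged", tab$q[i]))
  for (nm in names(nosat)[nosat])
    msgs <- c(msgs, sprintf(
      "%s: minimum at q_max (criterion may still be decreasing)", nm))
  list(slow_convergence = slow, underpopulated = under,
       not_converged = noconv, no_saturation = nosat, messages = msgs)
}

#' Write a selection result as TSV (and optionally JSON)
#'
#' @param result a `selection_result`.
#' @param tsv_path path for the criteria table TSV.
#' @param json_path optional path for a JSON document including the
#'   selections and flags.
#' @param config optional run configuration to embed in the JSON.
#' @export
write_selection <- function(result, tsv_path, json_path = NULL,
                            config = NULL) {
  utils::write.table(result$table, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    doc <- list(config = config, table = result$table,
                selection = result$selection,
                criterion_ordering = result$criterion_ordering,
                flags = result$flags$messages)
    writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                null = "null", dataframe = "rows"),
               json_path)
  }
  invisible(tsv_path)
}
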