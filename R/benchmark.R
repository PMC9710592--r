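#' Benchmark the untanglers on seeded random tanglegrams
#'
#' Generates `reps` random tanglegrams (see [generate_tanglegram()]) for
#' each tree size in `n_leaves`, runs every requested method on every
#' instance, and collects one record per (instance, method): seed, initial
#' and final entanglement, final crossings, shuffle depth reached (for the
#' shuffled methods) and entanglement evaluations. The whole grid is
#' deterministic given `seed`: instance `r` at size index `i` uses seed
#' `seed + 1000 * (i - 1) + (r - 1)`.
#'
#' @param n_leaves integer vector of tree sizes.
#' @param reps instances per size (`0` yields an empty table).
#' @param methods subset of `c("step2side", "stepbothsides", "shufs2s",
#'   "shuntan")`.
#' @param seed base seed (default 1).
#' @param cfg an [entanglement_config()].
#' @param mode generator mode, `"clustered"` (default) or
#'   `"random-topology"`.
#' @param m_cutoff optional shuffle-depth cutoff for the shuffled methods.
#' @param csv,json optional paths; when given, the per-instance records are
#'   written as CSV and the per-(size, method) mean-entanglement summary as
#'   JSON.
#' @return List with `records` (data frame, one row per instance/method)
#'   and `summary` (data frame of mean final entanglement by size and
#'   method).
#' @examples
#' b <- benchmark_untanglers(6, reps = 3, methods = c("step2side", "shuntan"))
#' b$summary
#' @export
benchmark_untanglers <- function(n_leaves, reps,
                                 methods = c("step2side", "stepbothsides",
                                             "shufs2s", "shuntan"),
                                 seed = 1L, cfg = entanglement_config(),
                                 mode = c("clustered", "random-topology"),
                                 m_cutoff = NULL, csv = NULL, json = NULL) {
  mode <- match.arg(mode)
  cfg <- as_cfg(cfg)
  known <- c("step2side", "stepbothsides", "shufs2s", "shuntan")
  methods <- tolower(methods)
  bad <- setdiff(methods, known)
  if (length(bad))
    stop("unknown method(s): ", paste(bad, collapse = ", "),
         " (choose from ", paste(known, collapse = ", "), ")", call. = FALSE)
  if (length(reps) != 1L || is.na(reps) || reps < 0L)
    stop("reps must be a single non-negative integer", call. = FALSE)
  rows <- list()
  for (i in seq_along(n_leaves)) {
    n <- n_leaves[i]
    for (r in seq_len(reps)) {
      inst_seed <- as.integer(seed) + 1000L * (i - 1L) + (r - 1L)
      L <- generate_tanglegram(n, mode = mode, seed = inst_seed)
      eps0 <- entanglement(L, cfg)
      for (meth in methods) {
        res <- untangle(L, meth, cfg, m_cutoff)
        rows[[length(rows) + 1L]] <- data.frame(
          n_leaves = n, seed = inst_seed, method = res$method,
          initial_entanglement = eps0,
          final_entanglement = res$entanglement,
          final_crossings = res$crossings,
          m_reached = if (is.null(res$trace$m_reached)) NA_integer_
                      else res$trace$m_reached,
          evaluations = res$trace$evaluations)
      }
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(n_leaves = integer(0), seed = integer(0), method = character(0),
               initial_entanglement = numeric(0), final_entanglement = numeric(0),
               final_crossings = integer(0), m_reached = integer(0),
               evaluations = numeric(0))
  summary <- if (nrow(records))
    aggregate(final_entanglement ~ n_leaves + method, records, mean) else
    data.frame(n_leaves = integer(0), method = character(0),
               final_entanglement = numeric(0))
  names(summary)[names(summary) == "final_entanglement"] <- "mean_entanglement"
  if (!is.null(csv))
    write.table(records, csv, sep = ",", row.names = FALSE, quote = FALSE)
  if (!is.null(json))
    jsonlite::write_json(summary, json, dataframe = "rows", digits = NA)
  list(records = records, summary = summary)
}
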