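## Chromatin-state annotation of DNAm probes and the variance-matched
## resampling enrichment test.

## run expr with a locally seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = .GlobalEnv))
          rm(".Random.seed", envir = .GlobalEnv)
      } else assign(".Random.seed", old, envir = .GlobalEnv)
    })
    set.seed(seed)
  }
  force(expr)
}

.strip_chr <- function(x) sub("^chr", "", x)

#' Read a chromatin-state collapse map
#'
#' Two-column tab-delimited file `raw_state<TAB>category` mapping raw
#' segmentation labels (e.g. the 25 ChromHMM states) to the main
#' functional categories (e.g. the 14 used for enrichment).
#'
#' @param path file path.
#' @return named character vector, names = raw labels.
#' @export
read_collapse_map <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(dt) < 2) stop("collapse map needs two columns")
  setNames(dt[[2]], dt[[1]])
}

#' Read chromatin-state BED track(s)
#'
#' BED is 0-based half-open with the raw state label in column 4; labels
#' are collapsed through `collapse_map` and intervals merged per category
#' within each track. Multiple paths are kept as separate tracks (e.g.
#' one per reference epigenome).
#'
#' @param paths one or more BED file paths.
#' @param collapse_map named character vector (raw label -> category) or
#'   a path accepted by [read_collapse_map()]. `NULL` keeps raw labels.
#' @return object of class `StateAnnotation`: list of `GRanges` (one per
#'   track) with a `category` metadata column, coordinates 1-based.
#' @export
read_bed_states <- function(paths, collapse_map = NULL) {
  if (is.character(collapse_map) && length(collapse_map) == 1 &&
      file.exists(collapse_map))
    collapse_map <- read_collapse_map(collapse_map)
  tracks <- lapply(paths, function(p) {
    gr <- rtracklayer::import(p, format = "BED")
    labels <- gr$name
    if (!is.null(collapse_map)) {
      unknown <- setdiff(unique(labels), names(collapse_map))
      if (length(unknown))
        stop("state label(s) without a collapse-map entry: ",
             paste(unknown, collapse = ", "))
      labels <- unname(collapse_map[labels])
    }
    gr$category <- labels
    ## merge adjacent/overlapping intervals of the same category
    parts <- lapply(split(gr, gr$category), GenomicRanges::reduce)
    merged <- unlist(GenomicRanges::GRangesList(parts))
    merged$category <- names(merged)
    names(merged) <- NULL
    GenomicRanges::sort(merged)
  })
  structure(list(tracks = tracks), class = "StateAnnotation")
}

#' @export
print.StateAnnotation <- function(x, ...) {
  cat(sprintf("StateAnnotation: %d track(s), %s categories\n",
              length(x$tracks),
              length(unique(unlist(lapply(x$tracks, function(g)
                g$category))))))
  invisible(x)
}

#' Assign a functional category to each probe
#'
#' Point query of each probe position against the annotation. With
#' several tracks the per-probe category is the majority vote across
#' tracks (ties broken alphabetically); positions covered by no interval
#' get `"unannotated"`. Within a track, overlapping intervals of
#' different categories are resolved toward the interval with the
#' smallest start (deterministic; does not occur in a proper
#' segmentation).
#'
#' @param probes probe annotation table (`probe_id, chrom, bp`).
#' @param ann a `StateAnnotation`.
#' @return named character vector probe_id -> category.
#' @export
assign_category <- function(probes, ann) {
  q <- GenomicRanges::GRanges(
    .strip_chr(probes$chrom),
    IRanges::IRanges(start = probes$bp, width = 1L))
  per_track <- vapply(ann$tracks, function(tr) {
    tr2 <- GenomicRanges::GRanges(
      .strip_chr(as.character(GenomicRanges::seqnames(tr))),
      IRanges::ranges(tr), category = tr$category)
    hit <- GenomicRanges::findOverlaps(q, tr2, select = "first")
    out <- rep("unannotated", length(q))
    out[!is.na(hit)] <- tr2$category[hit[!is.na(hit)]]
    out
  }, character(nrow(probes)))
  per_track <- matrix(per_track, nrow = nrow(probes))
  cats <- apply(per_track, 1, function(v) {
    tab <- sort(table(v), decreasing = TRUE)
    nm <- names(tab)[tab == max(tab)]
    sort(nm)[1]
  })
  setNames(cats, probes$probe_id)
}

#' Variance-matched random probe sample
#'
#' Bins the probe universe into `n_bins` equal-frequency variance bins
#' and, for each target probe, draws one probe uniformly from the
#' target's bin excluding the target itself, so the sampled set matches
#' the targets' DNAm-variance distribution. A bin containing only the
#' target falls back to the nearest nonempty bin (count reported in
#' `attr(x, "n_fallback")`).
#'
#' @param universe `data.table` with columns `probe_id`, `variance`.
#' @param targets character vector of target probe ids (all in universe).
#' @param n_bins number of variance bins (default 100, capped at the
#'   universe size).
#' @param rng_seed integer seed, or `NULL` to use the current RNG state.
#' @return character vector of sampled probe ids, same length as
#'   `targets`.
#' @export
variance_matched_sample <- function(universe, targets, n_bins = 100L,
                                    rng_seed = NULL) {
  if (!all(targets %in% universe$probe_id))
    stop("target probe(s) missing from universe")
  if (!all(is.finite(universe$variance)) || any(universe$variance < 0))
    stop("variances must be finite and >= 0")
  N <- nrow(universe)
  n_bins <- max(1L, min(as.integer(n_bins), N))
  rnk <- data.table::frank(universe$variance, ties.method = "first")
  bin <- pmin(ceiling(rnk * n_bins / N), n_bins)
  names(bin) <- universe$probe_id
  by_bin <- split(universe$probe_id, bin)

  .with_seed(rng_seed, {
    n_fallback <- 0L
    out <- vapply(targets, function(tg) {
      bidx <- bin[[tg]]
      pool <- setdiff(by_bin[[as.character(bidx)]], tg)
      if (length(pool) == 0L) {
        n_fallback <<- n_fallback + 1L
        occupied <- as.integer(names(by_bin))
        occupied <- occupied[vapply(by_bin, function(v)
          length(setdiff(v, tg)) > 0, logical(1))]
        bnear <- occupied[which.min(abs(occupied - bidx))]
        pool <- setdiff(by_bin[[as.character(bnear)]], tg)
      }
      pool[sample.int(length(pool), 1L)]
    }, character(1), USE.NAMES = FALSE)
    attr(out, "n_fallback") <- n_fallback
    out
  })
}

#' Variance-matched enrichment test of functional categories
#'
#' Compares the distribution of target probes over functional categories
#' with that of variance-matched random probe sets. The fold enrichment
#' per category is the observed target proportion divided by the mean
#' proportion over `n_fold_reps` matched null samples; its standard
#' error is the standard deviation of the per-replicate fold
#' (observed / replicate proportion) over the first `n_se_reps`
#' replicates. `z = (fold - 1)/se_fold` and its two-sided normal p-value
#' are reported as an explicitly approximate significance measure.
#'
#' @param targets character vector of target probe ids.
#' @param universe `data.table` with `probe_id`, `variance` covering all
#'   probes (targets included).
#' @param categories named character vector probe_id -> category from
#'   [assign_category()].
#' @param n_fold_reps null replicates for the fold estimate
#'   (default 500).
#' @param n_se_reps null replicates for the SE estimate (default 100;
#'   must not exceed `n_fold_reps`).
#' @param n_bins variance bins (default 100).
#' @param rng_seed integer seed for reproducibility.
#' @return `data.table` with columns `category, observed, null_mean,
#'   fold, se_fold, z, p_approx, flagged` (flagged when `null_mean` is 0
#'   or the SE is based on < `n_se_reps` finite replicates).
#' @export
enrichment_test <- function(targets, universe, categories,
                            n_fold_reps = 500L, n_se_reps = 100L,
                            n_bins = 100L, rng_seed = 1L) {
  stopifnot(n_fold_reps >= 2L, n_se_reps >= 2L,
            n_se_reps <= n_fold_reps)
  if (!all(universe$probe_id %in% names(categories)))
    stop("categories must cover the whole universe")
  cats <- sort(unique(categories[universe$probe_id]))
  prop_of <- function(ids) {
    tab <- table(factor(categories[ids], levels = cats))
    as.numeric(tab) / length(ids)
  }
  observed <- prop_of(targets)

  null_props <- matrix(NA_real_, nrow = n_fold_reps, ncol = length(cats))
  .with_seed(rng_seed, {
    for (r in seq_len(n_fold_reps)) {
      smp <- variance_matched_sample(universe, targets, n_bins = n_bins,
                                     rng_seed = NULL)
      null_props[r, ] <- prop_of(smp)
    }
  })
  null_mean <- colMeans(null_props)
  fold <- ifelse(null_mean > 0, observed / null_mean, NA_real_)

  se_fold <- z <- p_approx <- rep(NA_real_, length(cats))
  flagged <- null_mean == 0
  for (k in seq_along(cats)) {
    if (flagged[k]) next
    fr <- observed[k] / null_props[seq_len(n_se_reps), k]
    fr <- fr[is.finite(fr)]
    if (length(fr) < n_se_reps) flagged[k] <- TRUE
    if (length(fr) >= 2L) {
      se_fold[k] <- sd(fr)
      if (se_fold[k] > 0) {
        z[k] <- (fold[k] - 1) / se_fold[k]
        p_approx[k] <- 2 * pnorm(-abs(z[k]))
      }
    }
  }
  data.table::data.table(
    category = cats, observed = observed, null_mean = null_mean,
    fold = fold, se_fold = se_fold, z = z, p_approx = p_approx,
    flagged = flagged)
}
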