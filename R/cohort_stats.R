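#' Per-group mean and SD of every feature
#'
#' Aggregates a feature table to one row per (group, arm, fov, feature)
#' with n, mean and sample SD (denominator n - 1). Sentinel (`NaN`/`NA`)
#' feature values are excluded listwise per feature, with the exclusion
#' count reported; a single retained value yields `sd = NA` and a flag.
#'
#' @param features Feature table from [quantify_cohort()] (needs `group`,
#'   `arm`, `fov` columns plus the feature columns).
#' @param feature_cols Feature columns to aggregate.
#' @return Tibble: `group`, `arm`, `fov`, `feature`, `n`, `n_excluded`,
#'   `mean`, `sd`, `flagged`.
#' @export
summarize_features <- function(features,
                               feature_cols = c("bvd", "bvc", "bvt", "vpi")) {
  need <- c("group", "arm", "fov")
  if (!all(need %in% names(features))) {
    abort("`features` must have group, arm and fov columns")
  }
  long <- tidyr::pivot_longer(
    dplyr::select(features, dplyr::all_of(c(need, feature_cols))),
    cols = dplyr::all_of(feature_cols),
    names_to = "feature", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$group, .data$arm, .data$fov, .data$feature),
    n = sum(is.finite(.data$value)),
    n_excluded = sum(!is.finite(.data$value)),
    mean = if (any(is.finite(.data$value)))
      mean(.data$value[is.finite(.data$value)]) else NA_real_,
    sd = if (sum(is.finite(.data$value)) >= 2)
      sd(.data$value[is.finite(.data$value)]) else NA_real_,
    .groups = "drop")
  out$flagged <- out$n < 2
  out$feature <- factor(out$feature, levels = feature_cols)
  dplyr::arrange(out, .data$fov, .data$group, .data$feature, .data$arm)
}

#' Two-tailed t-test between the TR and GT arms
#'
#' Default is the unpaired Welch test (unequal variances); a paired test
#' is available since TR/GT values come from the same subjects, and a
#' pooled-variance unpaired test via `var_equal`. Degenerate input with
#' zero variance in both arms and equal means returns `t = 0, p = 1`
#' rather than an error.
#'
#' @param x_tr,x_gt Numeric vectors (paired mode requires equal length).
#' @param paired Paired test on per-subject differences?
#' @param var_equal Pool variances in the unpaired test?
#' @return One-row tibble: `t`, `df`, `p`, `method`, `n_tr`, `n_gt`.
#' @export
ttest_tr_vs_gt <- function(x_tr, x_gt, paired = FALSE, var_equal = FALSE) {
  x_tr <- x_tr[is.finite(x_tr)]
  x_gt <- x_gt[is.finite(x_gt)]
  if (length(x_tr) < 2 || length(x_gt) < 2) {
    abort("each arm needs at least 2 finite values")
  }
  if (paired && length(x_tr) != length(x_gt)) {
    abort("paired test requires equal-length arms")
  }
  method <- if (paired) "paired" else if (var_equal) "pooled" else "welch"
  degenerate <- if (paired) {
    sd(x_tr - x_gt) == 0
  } else {
    sd(x_tr) == 0 && sd(x_gt) == 0
  }
  if (degenerate) {
    delta <- if (paired) mean(x_tr - x_gt) else mean(x_tr) - mean(x_gt)
    if (delta == 0) {
      res <- list(t = 0, df = NA_real_, p = 1)
    } else {
      res <- list(t = sign(delta) * Inf, df = NA_real_, p = 0)
    }
  } else {
    ht <- t.test(x_tr, x_gt, paired = paired, var.equal = var_equal,
                 alternative = "two.sided")
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value)
  }
  tibble::tibble(t = res$t, df = res$df, p = res$p, method = method,
                 n_tr = length(x_tr), n_gt = length(x_gt))
}

#' Build the cohort comparison report
#'
#' Joins manifest, morphometry features and (optionally) quality metrics
#' into per-group mean/SD tables and per-(fov, feature) two-tailed TR vs
#' GT t-tests, Welch and paired both reported. Subjects with a missing
#' arm are listed as exclusions and the run continues. No
#' multiple-testing correction is applied; the number of tests is
#' reported so users can correct downstream.
#'
#' @param manifest Manifest tibble.
#' @param features Output of [quantify_cohort()].
#' @param quality Optional output of [quality_pairs()].
#' @param fid Optional output of [quality_fid()].
#' @param config A [run_config()] (recorded, with its hash, in the
#'   provenance block).
#' @return An `octa_report` list: `means`, `tests`, `quality_summary`,
#'   `fid`, `exclusions`, `n_tests`, `provenance`.
#' @export
build_report <- function(manifest, features, quality = NULL, fid = NULL,
                         config = run_config()) {
  feature_cols <- c("bvd", "bvc", "bvt", "vpi")
  gt_ids <- manifest$subject_id[manifest$arm == "GT"]
  tr_ids <- manifest$subject_id[manifest$arm == "TR"]
  excl <- tibble::tibble(
    subject_id = c(setdiff(gt_ids, tr_ids), setdiff(tr_ids, gt_ids)),
    reason = c(rep("missing TR arm", length(setdiff(gt_ids, tr_ids))),
               rep("missing GT arm", length(setdiff(tr_ids, gt_ids)))))
  paired_ids <- intersect(gt_ids, tr_ids)

  means <- summarize_features(features, feature_cols)

  wide <- dplyr::filter(features, .data$subject_id %in% paired_ids)
  tests <- purrr::map(unique(wide$fov), function(f) {
    sub <- dplyr::filter(wide, .data$fov == f)
    purrr::map(feature_cols, function(feat) {
      gt <- sub[sub$arm == "GT", ]
      tr <- sub[sub$arm == "TR", ]
      ord <- match(gt$subject_id, tr$subject_id)
      x_gt <- gt[[feat]]
      x_tr <- tr[[feat]][ord]
      ok <- is.finite(x_gt) & is.finite(x_tr)
      if (sum(ok) < 2) {
        return(tibble::tibble(fov = f, feature = feat, method = c("welch", "paired"),
                              t = NA_real_, df = NA_real_, p = NA_real_,
                              n = sum(ok), significant_at_0_05 = NA))
      }
      welch <- ttest_tr_vs_gt(x_tr[ok], x_gt[ok], paired = FALSE)
      pair <- ttest_tr_vs_gt(x_tr[ok], x_gt[ok], paired = TRUE)
      tibble::tibble(fov = f, feature = feat,
                     method = c("welch", "paired"),
                     t = c(welch$t, pair$t), df = c(welch$df, pair$df),
                     p = c(welch$p, pair$p), n = sum(ok),
                     significant_at_0_05 = c(welch$p, pair$p) < 0.05)
    })
  })
  tests <- dplyr::bind_rows(purrr::flatten(tests))

  quality_summary <- if (!is.null(quality)) {
    qcols <- intersect(c("ssim", "pcqi"), names(quality))
    long <- tidyr::pivot_longer(quality, dplyr::all_of(qcols),
                                names_to = "metric", values_to = "value")
    dplyr::summarise(dplyr::group_by(long, .data$fov, .data$metric),
                     n = dplyr::n(), mean = mean(.data$value),
                     sd = sd(.data$value), .groups = "drop")
  }

  structure(list(means = means, tests = tests,
                 quality_summary = quality_summary, fid = fid,
                 exclusions = excl,
                 n_tests = sum(tests$method == "welch"),
                 provenance = list(config = config,
                                   config_hash = config_hash(config),
                                   package_version = as.character(
                                     utils::packageVersion("octamorph")))),
            class = "octa_report")
}

#' @export
print.octa_report <- function(x, ...) {
  cat(sprintf("<octa_report> %d mean rows, %d t-tests (x2 methods), %d exclusions\n",
              nrow(x$means), x$n_tests, nrow(x$exclusions)))
  cat(sprintf("config %s, octamorph %s\n", x$provenance$config_hash,
              x$provenance$package_version))
  print(x$tests, n = 16)
  invisible(x)
}

#' Tidy the t-test table of a cohort report
#'
#' @param x An `octa_report`.
#' @param ... Unused.
#' @return The per-(fov, feature, method) t-test tibble.
#' @export
tidy.octa_report <- function(x, ...) {
  x$tests
}

#' One-row summary of a cohort report
#'
#' @param x An `octa_report`.
#' @param ... Unused.
#' @return Tibble with subject/test counts, the number of Welch tests
#'   significant at 0.05, and the config hash.
#' @export
glance.octa_report <- function(x, ...) {
  welch <- x$tests[x$tests$method == "welch", ]
  tibble::tibble(n_groups = length(unique(x$means$group)),
                 n_tests = x$n_tests,
                 n_significant = sum(welch$significant_at_0_05, na.rm = TRUE),
                 n_exclusions = nrow(x$exclusions),
                 config_hash = x$provenance$config_hash)
}
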