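#' Spectral-power subsequent memory effect
#'
#' Welch (unequal-variance) t-statistic per channel and frequency contrasting
#' encoding power features of later-recalled against not-recalled items.
#' Positive t means higher power during successful encoding.
#'
#' @param features A [encoding_power_features()] object.
#' @param recalled Logical vector, one flag per item (feature row).
#' @return An object of class `sme_result`: list with the `t_stats` matrix
#'   (channels x frequencies), `freqs`, `channels`, class counts.
#' @export
power_sme <- function(features, recalled) {
  stopifnot(inherits(features, "power_features"))
  recalled <- as.logical(recalled)
  stopifnot(length(recalled) == dim(features$values)[1])
  n_rec <- sum(recalled)
  n_not <- sum(!recalled)
  if (n_rec < 2 || n_not < 2) {
    abort("power_sme() needs at least two items in each class.")
  }
  d <- dim(features$values)
  flat <- matrix(features$values, nrow = d[1]) # columns: channel x freq
  wt <- welch_t(flat[recalled, , drop = FALSE], flat[!recalled, , drop = FALSE])
  t_stats <- matrix(
    wt$t, nrow = d[2], ncol = d[3],
    dimnames = list(features$channels, NULL)
  )
  structure(
    list(
      t_stats = t_stats, freqs = features$freqs, channels = features$channels,
      n_recalled = n_rec, n_not_recalled = n_not, window = features$window
    ),
    class = "sme_result"
  )
}

#' @export
print.sme_result <- function(x, ...) {
  cat(sprintf(
    "<sme_result> %d channels x %d freqs; %d recalled vs %d not\n",
    nrow(x$t_stats), ncol(x$t_stats), x$n_recalled, x$n_not_recalled
  ))
  invisible(x)
}

#' Default analysis bands
#'
#' Theta 4--8 Hz and high-frequency activity 45--170 Hz, as closed intervals
#' on the wavelet frequency grid.
#'
#' @return Named list of `c(lo, hi)` vectors.
#' @export
default_bands <- function() {
  list(theta = c(4, 8), hfa = c(45, 170))
}

#' Region-by-band aggregation of SME t-statistics
#'
#' Averages per-channel, per-frequency SME t-statistics over the channels of
#' each anatomical region and the grid frequencies inside each band (closed
#' intervals). Grid frequencies outside every band do not contribute.
#' Regions with no channel yield no row.
#'
#' @param sme An [power_sme()] result.
#' @param electrodes Electrode tibble for the analysed channels.
#' @param bands Named list of frequency intervals; see [default_bands()].
#' @return A tibble with `region`, `band`, `mean_t`, `n_channels`, `n_freqs`.
#' @export
band_region_sme <- function(sme, electrodes, bands = default_bands()) {
  stopifnot(inherits(sme, "sme_result"))
  assert_electrodes(electrodes)
  electrodes <- electrodes[match(sme$channels, electrodes$channel), ]
  if (anyNA(electrodes$channel)) {
    abort("Electrode table lacks some analysed channels.")
  }
  grid <- tidyr::expand_grid(
    region = unique(electrodes$region),
    band = names(bands)
  )
  res <- purrr::pmap(grid, function(region, band) {
    ch_idx <- which(electrodes$region == region)
    f_idx <- which(sme$freqs >= bands[[band]][1] & sme$freqs <= bands[[band]][2])
    tibble(
      region = region, band = band,
      mean_t = if (length(ch_idx) && length(f_idx)) {
        mean(sme$t_stats[ch_idx, f_idx])
      } else {
        NA_real_
      },
      n_channels = length(ch_idx), n_freqs = length(f_idx)
    )
  })
  list_rbind(res)
}

#' Group contrast of region-by-band SME cells
#'
#' Welch t-test between groups on each region x band mean SME t-statistic,
#' with Benjamini--Hochberg false-discovery-rate correction applied jointly
#' over all cells (8 with the default 4 regions x 2 bands).
#'
#' @param cells Tibble of per-subject cells: `subject`, `region`, `band`,
#'   `mean_t` (e.g. [band_region_sme()] results row-bound over subjects).
#' @param groups Tibble with `subject`, `group` (two levels, each with at
#'   least two subjects).
#' @return A tibble with `region`, `band`, group means, `t`, `df`, `p_value`,
#'   `q_value`.
#' @export
group_sme_contrast <- function(cells, groups) {
  d <- inner_join(cells, groups, by = "subject")
  gl <- sort(unique(d$group))
  if (length(gl) != 2) abort("Exactly two groups are required.")
  res <- d |>
    filter(!is.na(.data$mean_t)) |>
    summarise(
      mean_1 = mean(.data$mean_t[.data$group == gl[1]]),
      mean_2 = mean(.data$mean_t[.data$group == gl[2]]),
      n_1 = sum(.data$group == gl[1]),
      n_2 = sum(.data$group == gl[2]),
      .by = c("region", "band")
    )
  if (any(res$n_1 < 2) || any(res$n_2 < 2)) {
    abort("Each group needs at least two subjects per cell.")
  }
  stats <- d |>
    filter(!is.na(.data$mean_t)) |>
    group_by(.data$region, .data$band) |>
    group_modify(function(df, key) {
      wt <- welch_t(
        df$mean_t[df$group == gl[1]],
        df$mean_t[df$group == gl[2]]
      )
      tibble(t = wt$t, df = wt$df, p_value = wt$p)
    }) |>
    ungroup()
  out <- inner_join(res, stats, by = c("region", "band"))
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out
}
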