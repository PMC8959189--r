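#' Tumor composition from tumor sizes and immune fractions
#'
#' Converts per-timepoint tumor sizes and immune-cell fractions into
#' absolute cell counts using the cells/mm^3 scaling factor `alpha` and
#' the average cancer:immune:necrotic composition ratio of mouse breast
#' tumors.  For each time point \eqn{t_i}:
#' \deqn{TNC_i = \alpha \, size(t_i) / \overline{size}}
#' \deqn{TNIC_i = 0.04\,\alpha \, ratio(t_i) / \overline{ratio}}
#' \deqn{TNCC_i = \tfrac{191}{192}(TNC_i - TNIC_i), \quad
#'       TNNC_i = TNCC_i / 191}
#' where the bar denotes the mean over the time points and 191/192 is
#' the simplified cancer-to-(cancer+necrotic) ratio 0.955 : 0.005.
#' By construction `TNCC/TNNC = 191` and `TNIC + TNCC + TNNC = TNC`.
#'
#' The immune-fraction normalization mirrors the tumor-size one: each
#' time point's summed immune ratio is divided by the mean over the
#' time points.
#'
#' @param tumor_sizes positive numeric vector of per-timepoint tumor
#'   sizes (arbitrary units; only ratios enter).
#' @param immune_ratios per-timepoint total immune-cell fractions.
#' @param alpha cells/mm^3 scaling factor, default 45.
#' @param ratios length-3 cancer:immune:necrotic composition, summing
#'   to 1; default `c(0.955, 0.04, 0.005)`.
#' @return A tibble with columns `time`, `TNC`, `TNIC`, `TNCC`, `TNNC`.
#' @examples
#' tme_composition(c(10, 30, 55, 80), c(0.05, 0.04, 0.04, 0.03))
#' @export
tme_composition <- function(tumor_sizes, immune_ratios,
                            alpha = 45,
                            ratios = c(0.955, 0.04, 0.005)) {
  if (any(tumor_sizes <= 0)) {
    stop("tumor sizes must be positive", call. = FALSE)
  }
  if (length(immune_ratios) != length(tumor_sizes)) {
    stop("tumor_sizes and immune_ratios must have equal length",
         call. = FALSE)
  }
  if (abs(sum(ratios) - 1) > 1e-8) {
    stop("composition ratios must sum to 1", call. = FALSE)
  }
  cn_ratio <- ratios[1] / ratios[3]            # cancer : necrotic, e.g. 191
  TNC <- alpha * tumor_sizes / mean(tumor_sizes)
  TNIC <- ratios[2] * alpha * immune_ratios / mean(immune_ratios)
  TNCC <- cn_ratio / (cn_ratio + 1) * (TNC - TNIC)
  TNNC <- TNCC / cn_ratio
  tibble::tibble(
    time = seq_along(tumor_sizes),
    TNC = TNC, TNIC = TNIC, TNCC = TNCC, TNNC = TNNC
  )
}
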