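#' Trait association with phylogenetic grouping
#'
#' Correlates a species-level trait against species mean CDA, overall and
#' within phylogenetic groups, then combines the per-group correlation
#' signs with an exact sign test — a phylogenetically-independent-contrast
#' surrogate: one qualitative datum per independent group. A group
#' contributes a correlation when it has at least 3 species and a sign when
#' it has at least 2 (for two species the sign of the paired difference).
#'
#' @param data A data frame with one row per species.
#' @param cda,trait,group Column names (strings) for species mean CDA, the
#'   trait value, and the group label.
#' @param method Correlation method for the per-group and overall
#'   estimates.
#' @return A tibble (class `cda_grouped_assoc`) with one row per group:
#'   `group`, `n`, `estimate`, `sign`, `p_one`, `p_two`. Attributes carry
#'   the overall association and the cross-group sign test; [glance()]
#'   returns them as a one-row tibble.
#' @examples
#' panel <- simulate_trait_panel(seed = 1)
#' glance(grouped_trait_assoc(panel))
#' @export
grouped_trait_assoc <- function(data, cda = "mean_cda", trait = "trait",
                                group = "group",
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  x <- data[[cda]]
  y <- data[[trait]]
  g <- data[[group]]
  stopifnot(!is.null(x), !is.null(y), !is.null(g))
  if (length(x) < 3) {
    rlang::abort("need at least 3 species", class = "cdar_too_few")
  }
  per_group <- purrr::map_dfr(unique(g), function(gg) {
    sel <- g == gg
    n <- sum(sel)
    est <- NA_real_
    p1 <- NA_real_
    p2 <- NA_real_
    sgn <- NA_integer_
    if (n >= 3 && stats::sd(x[sel]) > 0 && stats::sd(y[sel]) > 0) {
      a <- cor_assoc(x[sel], y[sel], method)
      est <- a$estimate
      p1 <- a$p_one
      p2 <- a$p_two
      sgn <- sign(est)
    } else if (n == 2) {
      d <- diff(y[sel][order(x[sel])])
      if (d != 0) sgn <- as.integer(sign(d))
    }
    tibble::tibble(group = gg, n = n, estimate = est, sign = sgn, p_one = p1, p_two = p2)
  })
  signs <- per_group$sign[!is.na(per_group$sign) & per_group$sign != 0]
  if (length(signs) == 0) {
    rlang::abort("no group with a computable sign", class = "cdar_too_few")
  }
  overall <- cor_assoc(x, y, method)
  st <- sign_test(sum(signs < 0), length(signs))
  attr(per_group, "overall") <- overall
  attr(per_group, "sign_test") <- tibble::tibble(
    n_groups = length(signs),
    n_negative = sum(signs < 0),
    p_one = st$p_one,
    p_two = st$p_two
  )
  class(per_group) <- c("cda_grouped_assoc", class(per_group))
  per_group
}

#' @export
glance.cda_grouped_assoc <- function(x, ...) {
  ov <- attr(x, "overall")
  st <- attr(x, "sign_test")
  tibble::tibble(
    method = ov$method,
    estimate = ov$estimate,
    n = ov$n,
    p_one = ov$p_one,
    p_two = ov$p_two,
    n_groups = st$n_groups,
    n_negative_groups = st$n_negative,
    sign_p_one = st$p_one,
    sign_p_two = st$p_two
  )
}

#' Developmental stability from bilateral counts
#'
#' Estimates per-species developmental stability as the Pearson correlation
#' between left- and right-side counts of a bilateral meristic trait
#' (e.g. subdigital lamellae) across individuals. Species with fewer than
#' `min_pairs` individuals, or with constant counts on either side, return
#' `NA` with a warning. Associate the estimates with species mean CDA via
#' [grouped_trait_assoc()].
#'
#' @param data A data frame of individuals.
#' @param species,left,right Column names.
#' @param min_pairs Minimum individuals per species (default 3).
#' @return A tibble with `species`, `n`, `stability`.
#' @examples
#' d <- data.frame(
#'   species = rep("a", 4),
#'   left = c(10, 12, 11, 13), right = c(10, 12, 12, 13)
#' )
#' bilateral_stability(d)
#' @export
bilateral_stability <- function(data, species = "species", left = "left",
                                right = "right", min_pairs = 3) {
  purrr::map_dfr(unique(data[[species]]), function(sp) {
    sel <- data[[species]] == sp
    l <- data[[left]][sel]
    r <- data[[right]][sel]
    st <- NA_real_
    if (sum(sel) >= min_pairs) {
      if (stats::sd(l) == 0 || stats::sd(r) == 0) {
        rlang::warn(paste0("constant counts for species ", sp, "; stability undefined"))
      } else {
        st <- stats::cor(l, r)
      }
    }
    tibble::tibble(species = sp, n = sum(sel), stability = st)
  })
}

#' Positional mutation-pressure control
#'
#' Rank correlation of per-gene mean CDA against a user-supplied per-gene
#' exposure value (time spent single-stranded during replication or
#' transcription) — the negative control for strand-asymmetric mutation
#' pressure shaping mean CDA.
#'
#' @param gene_cda A data frame with columns `gene` and `mean_cda`.
#' @param exposure A data frame with columns `gene` and `exposure`.
#' @param method Correlation method (default `"spearman"`).
#' @return A one-row tibble as in [cor_assoc()].
#' @examples
#' positional_control_assoc(
#'   data.frame(gene = c("a", "b", "c"), mean_cda = c(-0.1, 0, 0.1)),
#'   data.frame(gene = c("a", "b", "c"), exposure = c(3, 2, 1))
#' )
#' @export
positional_control_assoc <- function(gene_cda, exposure,
                                     method = c("spearman", "pearson")) {
  method <- match.arg(method)
  merged <- dplyr::inner_join(gene_cda, exposure, by = "gene")
  if (nrow(merged) < length(unique(c(gene_cda$gene, exposure$gene)))) {
    rlang::abort("gene sets do not match", class = "cdar_bad_input")
  }
  cor_assoc(merged$mean_cda, merged$exposure, method)
}
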