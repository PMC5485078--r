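# ggplot2 displays for the main result types.

#' @export
autoplot.axevol_ols <- function(object, ...) {
  if (length(object$predictors) > 1) {
    abort("autoplot supports single-predictor fits; plot terms individually.")
  }
  x <- object$predictors[1]
  y <- object$response
  slope <- object$coefficients$estimate[match(
    object$coefficients$term, sprintf("`%s`", x)
  )]
  if (all(is.na(slope))) slope <- object$coefficients$estimate[nrow(object$coefficients)]
  slope <- slope[!is.na(slope)][1]
  intercept <- if (object$through_origin) {
    0
  } else {
    object$coefficients$estimate[object$coefficients$term == "(Intercept)"]
  }
  lab <- if (object$through_origin) "standardized PIC" else "observed value"
  ggplot2::ggplot(
    object$data,
    ggplot2::aes(x = .data[[x]], y = .data[[y]])
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = slope, intercept = intercept, color = "#2166ac") +
    ggplot2::labs(
      x = paste(x, sprintf("(%s)", lab)), y = paste(y, sprintf("(%s)", lab)),
      subtitle = sprintf("R² = %.3f, n = %d", object$r.squared, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.axevol_decomposition <- function(object, ...) {
  logged <- isTRUE(attr(object, "logged"))
  ref_slope <- if (logged) 1 else -1
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cervical, y = .data$dorsal)) +
    ggplot2::geom_abline(slope = -1, intercept = 0, linetype = "dashed", color = "gray50") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "gray75") +
    ggplot2::geom_point(ggplot2::aes(color = .data$pure), alpha = 0.8) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "gray20")) +
    ggplot2::labs(
      x = if (logged) "PIC of log cervical count" else "PIC of cervical count",
      y = if (logged) "PIC of log dorsal count" else "PIC of dorsal count",
      color = if (logged) "pure somitogenetic" else "pure homeotic",
      subtitle = sprintf(
        "reference diagonal: d = %sc (%s change)",
        if (ref_slope < 0) "-" else "",
        if (logged) "pure somitogenetic" else "pure homeotic"
      )
    ) +
    ggplot2::theme_minimal()
}

# simple rectangular layout: x = node age (reversed), y = tip order
tree_segments <- function(tree) {
  ntip <- ape::Ntip(tree)
  age <- node_ages(tree)$age
  yy <- rep(NA_real_, ntip + tree$Nnode)
  yy[seq_len(ntip)] <- seq_len(ntip)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq(1, nrow(po), by = 2)) {
    p <- po[i, 1]
    yy[p] <- mean(yy[po[i:(i + 1), 2]])
  }
  tibble(
    edge = match(
      paste(tree$edge[, 1], tree$edge[, 2]),
      paste(tree$edge[, 1], tree$edge[, 2])
    ),
    x0 = age[tree$edge[, 1]], x1 = age[tree$edge[, 2]],
    y0 = yy[tree$edge[, 2]], y1 = yy[tree$edge[, 2]],
    yp = yy[tree$edge[, 1]]
  )
}

#' Plot per-branch posterior rates on the tree
#'
#' Draws the time tree with branches colored by their posterior rate class:
#' red above the tree-wide median rate, blue below, gray where the credible
#' interval straddles it.
#'
#' @param chain a `posterior_chain` (post burn-in; combine chains first).
#' @param prob credible-interval mass for the classification.
#' @return A ggplot object.
#' @export
plot_branch_rates <- function(chain, prob = 0.9) {
  summ <- branch_rate_summary(chain, prob = prob)
  seg <- tree_segments(chain$tree)
  seg$class <- summ$class[match(chain$tree$edge[, 2], summ$child)]
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x0, xend = .data$x1, y = .data$y0, yend = .data$y1, color = .data$class)
    ) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x0, xend = .data$x0, y = .data$yp, yend = .data$y0, color = .data$class)
    ) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_color_manual(
      values = c(above = "#b2182b", below = "#2166ac", at = "gray60")
    ) +
    ggplot2::labs(x = "age (Ma)", y = NULL, color = "rate vs median") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      panel.grid.major.y = ggplot2::element_blank(),
      panel.grid.minor.y = ggplot2::element_blank()
    )
}
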