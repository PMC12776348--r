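#' Heatmap of a mutual hazard network
#'
#' Displays the trained parameters on the multiplicative scale
#' \eqn{\exp(\theta)}: base rates as a separate left column, the
#' \eqn{n \times n} matrix of rate multipliers (rows = affected event,
#' columns = influencing event; the diagonal is blank), and -- for
#' observation-aware models -- a bottom row with each event's multiplier
#' on the observation rate.  Cells are annotated with the multiplier
#' rounded to 2 decimals on a diverging scale centered at 1 (no effect).
#'
#' @param model an \code{"mhn"} model.
#' @param path optional output image path (\code{.png} or \code{.pdf});
#'   when \code{NULL} the ggplot object is returned for on-screen display.
#' @param width,height device size in inches.
#' @return the ggplot object, invisibly when written to \code{path}.
#' @export
render_heatmap <- function(model, path = NULL, width = NULL, height = NULL) {
  stopifnot(inherits(model, "mhn"))
  th <- model$log_theta
  n <- model$n
  ev <- model$events
  aware <- model$kind != "classic"
  rows <- c(ev, if (aware) "observation")
  cols <- c("base rate", ev)
  cells <- expand.grid(row = rows, col = cols,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$log_value <- NA_real_
  for (i in seq_len(nrow(cells))) {
    r <- cells$row[i]
    cl <- cells$col[i]
    if (cl == "base rate") {
      if (r != "observation")
        cells$log_value[i] <- th[match(r, ev), match(r, ev)]
      # observation base rate is fixed to 1 and not displayed
    } else if (r == "observation") {
      cells$log_value[i] <- th[n + 1L, match(cl, ev)]
    } else if (r != cl) {
      cells$log_value[i] <- th[match(r, ev), match(cl, ev)]
    }
  }
  cells$label <- ifelse(is.na(cells$log_value), "",
                        sprintf("%.2f", exp(cells$log_value)))
  cells$row <- factor(cells$row, levels = rev(rows))
  cells$col <- factor(cells$col, levels = cols)
  lim <- max(abs(cells$log_value), 0.1, na.rm = TRUE)
  p <- ggplot2::ggplot(cells,
                       ggplot2::aes(x = .data$col, y = .data$row,
                                    fill = .data$log_value)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = c(-lim, lim),
                                  na.value = "grey92",
                                  name = "log multiplier") +
    ggplot2::geom_vline(xintercept = 1.5, linewidth = 0.8) +
    ggplot2::labs(x = "influencing event", y = "affected event") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (is.null(path))
    return(p)
  if (is.null(width)) width <- 1.5 + 0.45 * (n + 1)
  if (is.null(height)) height <- 1 + 0.45 * (n + 1 + aware)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(p)
}

#' @export
plot.mhn <- function(x, ...) {
  render_heatmap(x, path = NULL)
}
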