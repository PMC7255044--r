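#' Plot a clustered FLIM image or its lifetime signatures
#'
#' `type = "image"` draws the false-color cluster map (masked pixels white);
#' `type = "fls"` draws the accumulated per-cluster decay curves on a log
#' count axis, colored by cluster.
#'
#' @param object A `cluster_flim` object.
#' @param type `"image"` or `"fls"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_flim <- function(object, type = c("image", "fls"), ...) {
  type <- match.arg(type)
  if (type == "image") {
    lab <- object$labels
    df <- tibble(
      row = rep(seq_len(nrow(lab)), times = ncol(lab)),
      col = rep(seq_len(ncol(lab)), each = nrow(lab)),
      color = ifelse(is.na(as.vector(lab)), "#FFFFFF",
                     object$palette[as.vector(lab)])
    )
    ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$color)) +
      geom_raster() +
      scale_fill_identity() +
      coord_equal(expand = FALSE) +
      labs(x = NULL, y = NULL) +
      theme_minimal() +
      theme(axis.text = element_blank(), panel.grid = element_blank())
  } else {
    n_ch <- ncol(object$fls)
    t_ns <- (seq_len(n_ch) - 0.5) * object$channel_width_ps / 1000
    df <- tibble(
      cluster = factor(rep(seq_len(object$k), each = n_ch)),
      time_ns = rep(t_ns, times = object$k),
      counts = as.vector(t(object$fls))
    )
    ggplot(df[df$counts > 0, ],
           aes(x = .data$time_ns, y = .data$counts, color = .data$cluster)) +
      geom_line() +
      scale_color_manual(values = object$palette[seq_len(object$k)]) +
      scale_y_log10() +
      labs(x = "time (ns)", y = "accumulated counts (FLS)") +
      theme_minimal()
  }
}
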