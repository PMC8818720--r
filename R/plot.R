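#' Plot a flatmap
#'
#' Renders a flatmap channel (or the vector magnitude) as a raster with the
#' circumferential index U on the vertical axis and the longitudinal index V
#' on the horizontal axis, masking invalid nodes. Returns a ggplot object
#' when ggplot2 is installed, otherwise draws with base graphics.
#'
#' @param fm a [flatmap()].
#' @param channel channel index, or `NULL` for the magnitude of a 3-channel
#'   map (a 1-channel map is drawn directly).
#' @param title plot title.
#' @export
plot_flatmap <- function(fm, channel = NULL, title = NULL) {
  stopifnot(inherits(fm, "flatmap"))
  d <- dim(fm$values)
  img <- if (!is.null(channel)) fm$values[, , channel]
  else if (d[3] == 1L) fm$values[, , 1] else flatmap_magnitude(fm)
  img[!fm$mask] <- NA
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    df <- data.frame(U = rep(seq_len(d[1]), d[2]),
                     V = rep(seq_len(d[2]), each = d[1]),
                     value = as.vector(img))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$V, y = .data$U,
                                     fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(na.value = "grey85") +
      ggplot2::coord_fixed() +
      ggplot2::labs(title = title, x = "V (longitudinal)",
                    y = "U (circumferential)") +
      ggplot2::theme_minimal()
  } else {
    graphics::image(t(img), main = title, xlab = "V", ylab = "U",
                    useRaster = TRUE)
    invisible(NULL)
  }
}

#' Plot training history
#'
#' Train and validation loss per epoch for a trained network.
#'
#' @param net a `wss_net` with a `history` element.
#' @export
plot_training_history <- function(net) {
  h <- net$history
  if (is.null(h)) stop("network has no training history")
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    df <- rbind(data.frame(epoch = h$epoch, loss = h$train_loss,
                           set = "train"),
                data.frame(epoch = h$epoch, loss = h$val_loss, set = "val"))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$set)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "epoch", y = "loss") +
      ggplot2::theme_minimal()
  } else {
    graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                   ylab = "loss")
    graphics::lines(h$epoch, h$val_loss, lty = 2)
    invisible(NULL)
  }
}
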