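# Post-classification cleanup of a land-cover map and confusion-matrix
# accuracy statistics. The classifier producing the map is external; these
# tools operate on its output.

# internal: label 4- or 8-connected components of a logical matrix.
# Iterative BFS (no recursion limits); returns an integer matrix, 0 = FALSE.
label_components <- function(mask, connectivity = 4) {
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    expand.grid(dr = -1:1, dc = -1:1) |>
      (\(d) d[!(d$dr == 0 & d$dc == 0), ])() |>
      (\(d) split(as.matrix(d), seq_len(nrow(d))))() |>
      lapply(as.numeric)
  }
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]
      queue <- queue[-1]
      pr <- (p - 1L) %% nr + 1L
      pc <- (p - 1L) %/% nr + 1L
      for (o in offs) {
        qr <- pr + o[1]
        qc <- pc + o[2]
        if (qr >= 1 && qr <= nr && qc >= 1 && qc <= nc) {
          q <- (qc - 1L) * nr + qr
          if (mask[q] && labels[q] == 0L) {
            labels[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  labels
}

#' Remove small objects of a class from a classified raster
#'
#' Deletes every 4-connected component of `target_class` smaller than
#' `min_pixels` and refills its pixels from the surrounding map: each
#' removed pixel takes the modal class of its non-target 8-neighbours, with
#' ties (or an empty neighbourhood) resolved by the class of the nearest
#' non-target pixel in Euclidean distance. Components of size >=
#' `min_pixels` and all other classes are untouched, so the operation is
#' idempotent.
#'
#' @param class_mat Integer matrix of class codes (`NA` = nodata).
#' @param target_class The class whose small objects are removed.
#' @param min_pixels Components strictly smaller than this are removed
#'   (default 4: 3-pixel blobs go, 4-pixel blobs stay).
#' @param connectivity 4 (default) or 8.
#' @return The cleaned class matrix.
#' @export
#' @examples
#' m <- matrix(2L, 5, 5); m[2, 2:3] <- 1L   # 2-pixel rice blob in forest
#' remove_small_objects(m, target_class = 1L)[2, 2:3]
remove_small_objects <- function(class_mat, target_class, min_pixels = 4,
                                 connectivity = 4) {
  if (!is.matrix(class_mat)) {
    abort("`class_mat` must be a matrix of class codes.",
          class = "sistr_invalid_input")
  }
  mask <- !is.na(class_mat) & class_mat == target_class
  labels <- label_components(mask, connectivity)
  sizes <- tabulate(labels)
  small <- which(sizes > 0 & sizes < min_pixels)
  if (length(small) == 0) return(class_mat)

  out <- class_mat
  nr <- nrow(class_mat)
  nc <- ncol(class_mat)
  nontarget <- which(!mask & !is.na(class_mat), arr.ind = TRUE)
  for (comp in small) {
    for (p in which(labels == comp)) {
      pr <- (p - 1L) %% nr + 1L
      pc <- (p - 1L) %/% nr + 1L
      # classes of non-target 8-neighbours (original map)
      nb <- expand.grid(r = pr + (-1:1), c = pc + (-1:1))
      nb <- nb[(nb$r != pr | nb$c != pc) & nb$r >= 1 & nb$r <= nr &
                 nb$c >= 1 & nb$c <= nc, ]
      cls <- class_mat[cbind(nb$r, nb$c)]
      cls <- cls[!is.na(cls) & cls != target_class]
      fill <- NA_integer_
      if (length(cls) > 0) {
        tab <- table(cls)
        winners <- as.integer(names(tab)[tab == max(tab)])
        fill <- if (length(winners) == 1) winners else
          nearest_class(pr, pc, nontarget, class_mat, winners)
      } else if (nrow(nontarget) > 0) {
        fill <- nearest_class(pr, pc, nontarget, class_mat, NULL)
      }
      out[pr, pc] <- fill
    }
  }
  out
}

# internal: class of the nearest non-target pixel, optionally restricted to
# candidate classes; remaining ties broken by smallest class code.
nearest_class <- function(pr, pc, nontarget, class_mat, candidates) {
  cls <- class_mat[nontarget]
  keep <- if (is.null(candidates)) rep(TRUE, length(cls)) else
    cls %in% candidates
  if (!any(keep)) return(NA_integer_)
  d2 <- (nontarget[keep, 1] - pr)^2 + (nontarget[keep, 2] - pc)^2
  cand <- cls[keep][d2 == min(d2)]
  min(cand)
}

#' Accuracy statistics from a confusion matrix
#'
#' Rows are the mapped class, columns the reference class. Computes overall
#' accuracy (trace over total), Cohen's kappa
#' \eqn{(p_o - p_e)/(1 - p_e)} with chance agreement
#' \eqn{p_e = \sum_c \mathrm{row}_c \mathrm{col}_c / N^2}, and per-class
#' user's accuracy (diagonal over row total) and producer's accuracy
#' (diagonal over column total). Accuracies are reported in percent, kappa
#' as a ratio. A class with a zero row or column total gets `NA` for the
#' corresponding accuracy (undefined, not zero).
#'
#' @param cm Square numeric matrix of counts, with identical row and column
#'   class labels (dimnames) or none.
#' @return An object of class `sist_accuracy`: list with
#'   `overall_accuracy` (percent), `kappa`, and a `by_class` tibble with
#'   `class`, `users_accuracy`, `producers_accuracy` (percent). Has
#'   [tidy()] and [glance()] methods.
#' @export
#' @examples
#' cm <- diag(c(10, 20, 30))
#' glance(accuracy_metrics(cm))  # OA 100, kappa 1
accuracy_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || any(cm < 0) || sum(cm) <= 0 ||
      any(!is.finite(cm))) {
    abort("`cm` must be a square non-negative count matrix with total > 0.",
          class = "sistr_invalid_input")
  }
  labels <- rownames(cm)
  if (is.null(labels)) labels <- paste0("class_", seq_len(nrow(cm)))
  total <- sum(cm)
  rowt <- rowSums(cm)
  colt <- colSums(cm)
  po <- sum(diag(cm)) / total
  pe <- sum(rowt * colt) / total^2
  ua <- ifelse(rowt > 0, diag(cm) / rowt * 100, NA_real_)
  pa <- ifelse(colt > 0, diag(cm) / colt * 100, NA_real_)
  structure(
    list(overall_accuracy = po * 100,
         kappa = (po - pe) / (1 - pe),
         by_class = tibble(class = labels,
                           users_accuracy = unname(ua),
                           producers_accuracy = unname(pa)),
         n = total),
    class = "sist_accuracy"
  )
}

#' @export
print.sist_accuracy <- function(x, ...) {
  cat(sprintf("Overall accuracy %.2f%%   Cohen's kappa %.4f   (n = %g)\n",
              x$overall_accuracy, x$kappa, x$n))
  print(x$by_class)
  invisible(x)
}

#' @export
tidy.sist_accuracy <- function(x, ...) x$by_class

#' @export
glance.sist_accuracy <- function(x, ...) {
  tibble(overall_accuracy = x$overall_accuracy, kappa = x$kappa, n = x$n)
}

#' Read / write a confusion matrix CSV
#'
#' The CSV carries class labels as header row and first column; rows are
#' the mapped class, columns the reference class.
#'
#' @param path File path.
#' @return `read_confusion_csv()`: a labelled integer matrix.
#' @export
read_confusion_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @param cm Matrix to write.
#' @rdname read_confusion_csv
#' @export
write_confusion_csv <- function(cm, path) {
  df <- data.frame(class = rownames(cm), cm, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}
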