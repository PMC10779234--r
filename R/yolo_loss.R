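#' Grid-cell detection target for the reference loss
#'
#' The image is divided into S x S grid cells with beta box predictors per
#' cell. \code{obj[i, j, b] = 1} marks predictor b of cell (i, j) as
#' responsible for an object; at most one predictor per object-bearing
#' cell. True and predicted box centers (x, y), sizes (w, h) and
#' confidences C live in arrays of the same S x S x beta shape. The loss
#' weights default to lambda_coord = 5 and lambda_noobj = 0.5.
#'
#' @param S grid size (cells per side).
#' @param beta box predictors per cell.
#' @param obj 0/1 responsibility indicator array (S x S x beta).
#' @param truth,pred lists of arrays x, y, w, h, C (each S x S x beta).
#' @param lambda_coord,lambda_noobj loss weights.
#' @return a \code{grid_target} list.
#' @export
grid_target <- function(S, beta, obj, truth, pred,
                        lambda_coord = 5, lambda_noobj = 0.5) {
  dims <- c(S, S, beta)
  check <- function(a, nm) {
    if (!all(dim(a) == dims))
      stop(sprintf("%s must be an S x S x beta array", nm))
    a
  }
  obj <- check(obj, "obj")
  if (!all(obj %in% c(0, 1))) stop("obj must be 0/1")
  resp_per_cell <- apply(obj, c(1, 2), sum)
  if (any(resp_per_cell > 1))
    stop("at most one responsible predictor per cell")
  for (nm in c("x", "y", "w", "h", "C")) {
    truth[[nm]] <- check(truth[[nm]], paste0("truth$", nm))
    pred[[nm]] <- check(pred[[nm]], paste0("pred$", nm))
  }
  structure(list(S = as.integer(S), beta = as.integer(beta), obj = obj,
                 truth = truth, pred = pred, lambda_coord = lambda_coord,
                 lambda_noobj = lambda_noobj),
            class = "grid_target")
}

#' Number of values in the prediction tensor
#'
#' Each of the S*S cells predicts beta boxes of 5 values (x, y, w, h, C):
#' S * S * beta * 5 computations per image.
#'
#' @param target a \code{grid_target}.
#' @return integer count.
#' @export
prediction_count <- function(target) {
  target$S * target$S * target$beta * 5L
}

#' Center-coordinate loss
#'
#' \deqn{\lambda_{coord} \sum_i \sum_j l^{obj}_{ij} [(x - \hat x)^2 +
#' (y - \hat y)^2]} over responsible predictors only.
#'
#' @param target a \code{grid_target}.
#' @return non-negative loss value.
#' @export
coord_loss <- function(target) {
  with(target, lambda_coord * sum(obj * ((truth$x - pred$x)^2 +
                                           (truth$y - pred$y)^2)))
}

#' Box-size loss
#'
#' \deqn{\lambda_{coord} \sum_i \sum_j l^{obj}_{ij} [(w - \hat w)^2 +
#' (h - \hat h)^2]} as printed; \code{canonical = TRUE} uses the square-root
#' variant \eqn{(\sqrt w - \sqrt{\hat w})^2 + (\sqrt h - \sqrt{\hat h})^2}
#' of the original grid-cell detector.
#'
#' @param target a \code{grid_target}.
#' @param canonical use square-rooted sizes.
#' @return non-negative loss value.
#' @export
size_loss <- function(target, canonical = FALSE) {
  f <- if (canonical) sqrt else identity
  with(target, lambda_coord * sum(obj * ((f(truth$w) - f(pred$w))^2 +
                                           (f(truth$h) - f(pred$h))^2)))
}

#' Confidence loss
#'
#' \deqn{\lambda_{coord} \sum l^{obj}_{ij} (C - \hat C)^2 +
#' \lambda_{noobj} \sum l^{noobj}_{ij} (C - \hat C)^2} with
#' \eqn{l^{noobj} = 1 - l^{obj}}, exactly as printed: the object term is
#' weighted by lambda_coord. The canonical grid-cell detector weights it by
#' 1 instead (\code{canonical = TRUE}).
#'
#' @param target a \code{grid_target}.
#' @param canonical weight the object term by 1 instead of lambda_coord.
#' @return non-negative loss value.
#' @export
confidence_loss <- function(target, canonical = FALSE) {
  with(target, {
    w_obj <- if (canonical) 1 else lambda_coord
    w_obj * sum(obj * (truth$C - pred$C)^2) +
      lambda_noobj * sum((1 - obj) * (truth$C - pred$C)^2)
  })
}

#' Total composite loss
#'
#' Sum of the coordinate, size and confidence terms.
#'
#' @param target a \code{grid_target}.
#' @param canonical apply the canonical variants of the size and confidence
#'   terms.
#' @return non-negative loss; zero iff every responsible prediction matches
#'   its target and every empty predictor matches its (zero) confidence
#'   target.
#' @export
total_loss <- function(target, canonical = FALSE) {
  coord_loss(target) + size_loss(target, canonical) +
    confidence_loss(target, canonical)
}

#' A small random grid target (testing / demonstration helper)
#'
#' @param S,beta grid dimensions.
#' @param n_objects number of responsible predictors to place.
#' @param seed integer.
#' @param perfect make predictions equal to truth (zero loss).
#' @return a \code{grid_target}.
#' @export
random_grid_target <- function(S = 4L, beta = 2L, n_objects = 3L, seed = 1L,
                               perfect = FALSE) {
  with_seed(seed, {
    obj <- array(0, dim = c(S, S, beta))
    cells <- sample.int(S * S, min(n_objects, S * S))
    for (cc in cells) {
      i <- (cc - 1L) %% S + 1L; j <- (cc - 1L) %/% S + 1L
      obj[i, j, sample.int(beta, 1L)] <- 1
    }
    rand_set <- function() list(x = array(stats::runif(S * S * beta), c(S, S, beta)),
                                y = array(stats::runif(S * S * beta), c(S, S, beta)),
                                w = array(stats::runif(S * S * beta), c(S, S, beta)),
                                h = array(stats::runif(S * S * beta), c(S, S, beta)),
                                C = array(stats::runif(S * S * beta), c(S, S, beta)))
    truth <- rand_set()
    truth$C <- obj  # confidence target: 1 where responsible, else 0
    pred <- if (perfect) truth else rand_set()
    grid_target(S, beta, obj, truth, pred)
  })
}
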