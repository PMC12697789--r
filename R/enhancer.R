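# Toy-scale profile enhancement: an adversarial mapping from landmark-assay
# profiles to RNA-seq-like profiles (CycleGAN scheme: two generators, two
# least-squares discriminators, cycle-consistency loss), followed by a fully
# connected extrapolator from the landmark space (978 genes) to the
# genome-wide space (23614 genes). Both are implemented at configurable
# dimension so the stage is testable at desk scale.
#
# The adversarial objective is implemented in its printed (label-flipped)
# least-squares form, L = E[D(y)^2] + E[(1 - D(G(x)))^2], which drives real
# discriminator outputs toward 0 and fake ones toward 1; the standard
# convention (real -> 1, fake -> 0) is available via `convention`.

#' Least-squares adversarial loss
#'
#' @param d_real discriminator outputs on real target-domain samples.
#' @param d_fake discriminator outputs on generated samples `D(G(x))`.
#' @param convention `"as-printed"` (default; real target 0, fake target 1)
#'   or `"standard"` (real 1, fake 0).
#' @return scalar loss, always nonnegative.
#' @export
#' @examples
#' adversarial_loss(c(0, 0), c(1, 1))      # 0: the printed form's minimum
#' adversarial_loss(rep(0.5, 4), rep(0.5, 4))  # 0.25 + 0.25 = 0.5
adversarial_loss <- function(d_real, d_fake,
                             convention = c("as-printed", "standard")) {
  convention <- match.arg(convention)
  if (length(d_real) == 0 || length(d_fake) == 0)
    stop("discriminator output batches must be nonempty")
  if (any(!is.finite(d_real)) || any(!is.finite(d_fake)))
    stop("discriminator outputs must be finite")
  if (convention == "as-printed")
    mean(d_real^2) + mean((1 - d_fake)^2)
  else
    mean((1 - d_real)^2) + mean(d_fake^2)
}

mlp2_params <- function(d_in, hidden, d_out) {
  list(l1 = init_linear(d_in, hidden), l2 = init_linear(hidden, d_out))
}

mlp2_forward <- function(wp, X) {
  ag_linear(ag_linear_relu(X, wp$l1), wp$l2)
}

#' Train the adversarial landmark-to-RNA-seq enhancer
#'
#' Fits the CycleGAN scheme at toy dimension: generators `G: X -> Y` and
#' `F: Y -> X` plus least-squares discriminators on each domain, with
#' cycle-consistency weight `lambda_cycle`. Profile collections are unpaired
#' but must share the feature dimension.
#'
#' @param x_profiles,y_profiles numeric matrices (samples x dim) of source
#'   (landmark-like) and target (RNA-seq-like) profiles.
#' @param hidden generator/discriminator hidden width.
#' @param steps optimization steps (one generator and one discriminator
#'   update each).
#' @param batch_size samples drawn per domain per step.
#' @param lr Adam learning rate.
#' @param lambda_cycle cycle-consistency weight.
#' @param convention adversarial target convention, see [adversarial_loss()].
#' @param seed integer seed.
#' @return object of class `"enhancer"`: generator parameters, config and
#'   the logged loss trajectory (`$losses`, one row per step).
#' @export
train_enhancer <- function(x_profiles, y_profiles, hidden = 64, steps = 200,
                           batch_size = 32, lr = 1e-3, lambda_cycle = 1,
                           convention = c("as-printed", "standard"), seed = 1) {
  convention <- match.arg(convention)
  X <- as.matrix(x_profiles); Y <- as.matrix(y_profiles)
  if (nrow(X) == 0 || nrow(Y) == 0) stop("profile collections must be nonempty")
  if (ncol(X) != ncol(Y)) stop("profile collections must share the feature dimension")
  d <- ncol(X)
  set.seed(seed)
  params <- list(G = mlp2_params(d, hidden, d), F = mlp2_params(d, hidden, d),
                 DX = mlp2_params(d, hidden, 1), DY = mlp2_params(d, hidden, 1))
  # generator target for its own outputs: under the printed form the
  # generator drives D(G(x)) toward 0, under the standard form toward 1
  fake_target <- if (convention == "as-printed") 0 else 1
  opt_g <- adam_new(lr = lr)
  opt_d <- adam_new(lr = lr)
  log <- matrix(NA_real_, steps, 3,
                dimnames = list(NULL, c("adv_y", "adv_x", "cycle")))
  for (s in seq_len(steps)) {
    xb <- X[sample.int(nrow(X), min(batch_size, nrow(X))), , drop = FALSE]
    yb <- Y[sample.int(nrow(Y), min(batch_size, nrow(Y))), , drop = FALSE]
    # --- discriminator update (generators fixed)
    wp <- wrap_params(params)
    gx <- ag_value(mlp2_forward(wp$G, as_ag(xb)))
    fy <- ag_value(mlp2_forward(wp$F, as_ag(yb)))
    dy_real <- mlp2_forward(wp$DY, as_ag(yb))
    dy_fake <- mlp2_forward(wp$DY, as_ag(gx))
    dx_real <- mlp2_forward(wp$DX, as_ag(xb))
    dx_fake <- mlp2_forward(wp$DX, as_ag(fy))
    sq <- function(node, target) ag_mean(ag_square(ag_scale(ag_add(node,
      as_ag(matrix(-target, nrow(ag_value(node)), 1))), 1)))
    if (convention == "as-printed") {
      d_loss <- ag_add(ag_add(sq(dy_real, 0), sq(dy_fake, 1)),
                       ag_add(sq(dx_real, 0), sq(dx_fake, 1)))
    } else {
      d_loss <- ag_add(ag_add(sq(dy_real, 1), sq(dy_fake, 0)),
                       ag_add(sq(dx_real, 1), sq(dx_fake, 0)))
    }
    ag_backward(d_loss)
    params <- adam_step(opt_d, params, wp, trainable_prefix = c("DX", "DY"))
    log[s, 1] <- ag_value(sq(dy_real, 0))[1] + ag_value(sq(dy_fake, 1))[1]
    # --- generator update (discriminators fixed)
    wp <- wrap_params(params)
    gx <- mlp2_forward(wp$G, as_ag(xb))
    fy <- mlp2_forward(wp$F, as_ag(yb))
    dy_fake <- mlp2_forward(wp$DY, gx)
    dx_fake <- mlp2_forward(wp$DX, fy)
    cyc <- ag_add(ag_sse_rows_mean(mlp2_forward(wp$F, gx), as_ag(xb)),
                  ag_sse_rows_mean(mlp2_forward(wp$G, fy), as_ag(yb)))
    g_adv <- ag_add(sq(dy_fake, fake_target), sq(dx_fake, fake_target))
    g_loss <- ag_add(g_adv, ag_scale(cyc, lambda_cycle))
    ag_backward(g_loss)
    params <- adam_step(opt_g, params, wp, trainable_prefix = c("G", "F"))
    log[s, 2] <- ag_value(g_adv)[1]
    log[s, 3] <- ag_value(cyc)[1]
  }
  structure(list(params = params, dim = d, hidden = hidden,
                 convention = convention, losses = log),
            class = "enhancer")
}

#' Apply the trained enhancer generator
#'
#' @param profiles matrix or vector of landmark-space profiles.
#' @param enhancer a trained `"enhancer"`.
#' @return RNA-seq-like profile(s) of the same dimension.
#' @export
enhance <- function(profiles, enhancer) {
  single <- !is.matrix(profiles)
  X <- if (single) matrix(profiles, nrow = 1L) else as.matrix(profiles)
  if (ncol(X) != enhancer$dim)
    stop("profile length ", ncol(X), " does not match enhancer dimension ",
         enhancer$dim)
  out <- ag_value(mlp2_forward(wrap_params(enhancer$params$G), as_ag(X)))
  if (single) drop(out) else out
}

#' Construct (and optionally train) the landmark-to-genome extrapolator
#'
#' A single-hidden-layer fully connected network mapping landmark profiles
#' (length `l_dim`, default 978) to genome-wide profiles (length `w_dim`,
#' default 23614).
#'
#' @param l_dim,w_dim input and output dimensions.
#' @param hidden hidden width.
#' @param seed integer seed.
#' @return an untrained `"extrapolator"` handle.
#' @export
extrapolator_new <- function(l_dim = 978, w_dim = 23614, hidden = 64, seed = 1) {
  set.seed(seed)
  structure(list(params = mlp2_params(l_dim, hidden, w_dim),
                 l_dim = l_dim, w_dim = w_dim),
            class = "extrapolator")
}

#' Train the extrapolator on paired landmark / genome-wide profiles
#'
#' @param x landmark profiles (samples x l_dim).
#' @param y genome-wide profiles (samples x w_dim).
#' @param net an `"extrapolator"` (dimensions must match), or `NULL` to
#'   create one from the data dimensions.
#' @param epochs,batch_size,lr training hyperparameters.
#' @param seed integer seed.
#' @return the trained `"extrapolator"` with `$losses` per epoch.
#' @export
train_extrapolator <- function(x, y, net = NULL, epochs = 50, batch_size = 32,
                               lr = 1e-3, seed = 1) {
  X <- as.matrix(x); Y <- as.matrix(y)
  if (is.null(net)) net <- extrapolator_new(ncol(X), ncol(Y), seed = seed)
  if (ncol(X) != net$l_dim || ncol(Y) != net$w_dim)
    stop("training data dimensions do not match the extrapolator")
  set.seed(seed)
  params <- net$params
  opt <- adam_new(lr = lr)
  losses <- numeric(epochs)
  for (e in seq_len(epochs)) {
    ord <- sample.int(nrow(X))
    steps <- split(ord, ceiling(seq_along(ord) / batch_size))
    tot <- 0
    for (rows in steps) {
      wp <- wrap_params(params)
      yhat <- mlp2_forward(wp, as_ag(X[rows, , drop = FALSE]))
      loss <- ag_sse_rows_mean(yhat, as_ag(Y[rows, , drop = FALSE]))
      ag_backward(loss)
      params <- adam_step(opt, params, wp)
      tot <- tot + ag_value(loss)[1] * length(rows)
    }
    losses[e] <- tot / nrow(X)
  }
  net$params <- params
  net$losses <- losses
  net
}

#' Extrapolate a landmark profile to the genome-wide space
#'
#' @param landmark numeric vector of length `l_dim` (or matrix of profiles).
#' @param net an `"extrapolator"`.
#' @return numeric vector (or matrix) of length `w_dim`; deterministic.
#' @export
extrapolate <- function(landmark, net) {
  single <- !is.matrix(landmark)
  X <- if (single) matrix(landmark, nrow = 1L) else as.matrix(landmark)
  if (ncol(X) != net$l_dim)
    stop("landmark profile length ", ncol(X), " does not match input dimension ",
         net$l_dim)
  out <- ag_value(mlp2_forward(wrap_params(net$params), as_ag(X)))
  if (single) drop(out) else out
}
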