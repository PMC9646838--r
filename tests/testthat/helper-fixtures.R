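# Shared fixtures. Heavy artifacts (trained scorers, cohorts) are built once
# per test run and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small cohort + trained scorer for fast unit tests (32 px patches; exposed
# activation maps are 4x4).
unit_scorer <- function() {
  fixture("unit_scorer", function() {
    spec <- cohort_spec(n_slides_pos = 15, n_slides_neg = 15,
                        patches_per_slide = c(8, 16), lesion_fraction = 0.3,
                        patch_size = 32, seed = 421)
    slides <- generate_cohort(spec)
    imgs <- list(); labs <- integer()
    for (s in slides) {
      for (i in seq_along(s$patches)) {
        imgs[[length(imgs) + 1L]] <- s$patches[[i]]$img
        labs <- c(labs, as.integer(s$patch_truth[i]))
      }
    }
    model <- train_patch_model(imgs, labs,
                               patch_model_config(epochs = 6, seed = 19))
    list(spec = spec, slides = slides, imgs = imgs, labs = labs, model = model)
  })
}

# Hand-built activation bundle for unit tests of the representation maths.
manual_bundle <- function(activations, gradients, class_index = 1L) {
  structure(list(activations = activations, gradients = gradients,
                 class_index = class_index),
            class = "hm_activation_bundle")
}

# Central finite differences of the class objective with respect to the
# activations at `layer`, via forward passes only (independent of backprop).
fd_class_gradient <- function(net, x, layer, class_index = 1L, eps = 1e-3) {
  a <- hipomapr:::nn_activation_at(net, x, layer)
  a <- array(a, dim = dim(a)[1:3])
  fd <- array(0, dim = dim(a))
  for (i in seq_along(a)) {
    ap <- a; ap[i] <- ap[i] + eps
    am <- a; am[i] <- am[i] - eps
    pp <- hipomapr:::nn_forward_from(net, array(ap, dim = c(dim(a), 1L)), layer)
    pm <- hipomapr:::nn_forward_from(net, array(am, dim = c(dim(a), 1L)), layer)
    fd[i] <- (pp[1, class_index] - pm[1, class_index]) / (2 * eps)
  }
  fd
}

flatten_patches <- function(slides) {
  imgs <- list(); labs <- integer()
  for (s in slides) {
    for (i in seq_along(s$patches)) {
      imgs[[length(imgs) + 1L]] <- s$patches[[i]]$img
      labs <- c(labs, as.integer(s$patch_truth[i]))
    }
  }
  list(imgs = imgs, labs = labs)
}
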