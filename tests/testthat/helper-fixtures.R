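# Fixtures are generated in code under fixed seeds and cached for the session
# so expensive objects (scenes, chip sets) are built once.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# a mid-size scene with separated seeds (fast; scaled-down geometry)
scene_separated <- function() fixture("scene_sep", function() {
  generate_scene(scene_spec(width = 640, height = 480, n_seeds = 6,
                            adhesion_prob = 0, rng_seed = 7))
})

# a mid-size scene containing touching seeds
scene_touching <- function() fixture("scene_touch", function() {
  generate_scene(scene_spec(width = 640, height = 480, n_seeds = 6,
                            adhesion_prob = 0.8, rng_seed = 9))
})

# labeled chips for classifier / feature tests
chips_small <- function() fixture("chips_small", function() {
  synth_chips(60, rng_seed = 3)
})

# synthetic image with a dark disk on a bright background
disk_image <- function(H = 120, W = 140, cr = 60, cc = 70, r = 20,
                       bg = 230, fg = 90) {
  base <- outer(seq_len(H), seq_len(W),
                function(rr, cc2) ifelse((rr - cr)^2 + (cc2 - cc)^2 <= r^2, fg, bg))
  arr <- array(0, c(H, W, 4))
  for (ch in 1:4) arr[, , ch] <- base
  msimage(arr)
}

disk_mask <- function(H, W, cr, cc, r) {
  outer(seq_len(H), seq_len(W),
        function(rr, cc2) (rr - cr)^2 + (cc2 - cc)^2 <= r^2)
}

# brute-force softmax / cross-entropy oracles (high-precision direct formula)
softmax_brute <- function(z) {
  e <- exp(z)
  e / sum(e)
}

cross_entropy_brute <- function(probs, one_hot) {
  total <- 0
  for (i in seq_len(nrow(probs)))
    for (m in seq_len(ncol(probs)))
      if (one_hot[i, m] == 1) total <- total - log(probs[i, m])
  total
}
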