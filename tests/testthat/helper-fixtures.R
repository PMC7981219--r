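# Hand-constructed fixtures shared across test files.

# minimal sympatry matrix for a focal species with given sympatric partners
fake_sympatry <- function(species, focal, partners) {
  S <- matrix(FALSE, length(species), length(species),
              dimnames = list(species, species))
  S[focal, partners] <- TRUE
  N <- matrix(0L, length(species), length(species),
              dimnames = list(species, species))
  N[focal, partners] <- 10L
  diag(S) <- NA; diag(N) <- NA_integer_
  structure(list(species = species, S = S, N = N, threshold_km = 5,
                 min_points = 10, symmetrized = FALSE),
            class = "sympatry_matrix")
}

# classification with prescribed classes, bypassing the optimiser
fake_classes <- function(classes) {
  lv <- c("small", "medium", "large")
  cls <- factor(classes, levels = lv)
  names(cls) <- names(classes)
  structure(list(breaks = c(60, 85), class = cls,
                 counts = as.integer(table(cls)), class_names = lv,
                 within_ss = NA_real_,
                 traits = stats::setNames(rep(1, length(cls)), names(cls))),
            class = "size_classification")
}

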