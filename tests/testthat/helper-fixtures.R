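# shared fixture builders; everything is generated in code at test time

small_catalogue <- function(n = 30, seed = 3) {
  make_barcode_catalogue(sprintf("m%03d", seq_len(n)), seed = seed)
}

# mutate a barcode with a given number of random edit operations
mutate_barcode <- function(bc, n_ops, ops = c("sub", "del", "ins")) {
  ch <- strsplit(bc, "", fixed = TRUE)[[1]]
  for (k in seq_len(n_ops)) {
    op <- sample(ops, 1)
    pos <- sample(length(ch), 1)
    if (op == "sub") ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
    if (op == "del") ch <- ch[-pos]
    if (op == "ins") ch <- append(ch, sample(c("A", "C", "G", "T"), 1), after = pos)
  }
  paste(ch, collapse = "")
}

# random candidate generator mixing mutated real barcodes, random
# sequences, and boundary-budget constructions
random_candidate <- function(catalogue) {
  u <- runif(1)
  bcs <- catalogue$entries$up_barcode
  if (u < 0.55) {
    mutate_barcode(sample(bcs, 1), sample(0:5, 1))
  } else if (u < 0.7) { # boundary: exactly the printed budgets
    mutate_barcode(mutate_barcode(sample(bcs, 1), 2, "sub"), 3,
                   sample(c("del", "ins"), 1))
  } else if (u < 0.85) { # just past the budgets
    mutate_barcode(sample(bcs, 1), sample(3:4, 1), "sub")
  } else {
    paste(sample(c("A", "C", "G", "T"), sample(15:25, 1), TRUE), collapse = "")
  }
}

# noiseless piecewise-exponential curve with tiny inoculum and no
# background: the analytic limit of the lag geometry
clean_curve <- function(r1 = 0.5, r2 = 0.3, lag = 5, od0 = 1e-4,
                        od_switch = 0.4, distort = TRUE) {
  simulate_diauxic_curve(
    curve_design(od0 = od0, r1 = r1, r2 = r2,
                 t_switch = log(od_switch / od0) / r1, lag_true = lag,
                 noise_sd = 0, background = 0, distort = distort),
    seed = 1
  )
}
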