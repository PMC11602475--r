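## Shared fixtures, built in code at test time.

## Double-Gaussian-well free-energy curve: 20 kJ/mol central barrier with
## shallow interfacial wells, zero in bulk.
two_well <- function(z) {
  20 * exp(-z^2 / (2 * 0.8^2)) -
    5 * (exp(-(z - 1.8)^2 / (2 * 0.5^2)) + exp(-(z + 1.8)^2 / (2 * 0.5^2)))
}

## Small homogeneous composition: n POPC per leaflet (for dynamics tests).
flat_comp <- function(n_per_leaflet = 50) {
  build_native_composition(data.frame(
    leaflet = c("inner", "outer"),
    species = "POPC",
    count = n_per_leaflet))
}

## Brute-force O(N^2) hydrogen-bond oracle: every donor x acceptor pair,
## explicit loops, minimum-image distances.
hbond_bruteforce <- function(frame, donors, acceptors, criteria) {
  hits <- 0L
  for (i in seq_len(nrow(donors))) {
    D <- frame$coords[donors$D[i], ]
    H <- frame$coords[donors$H[i], ]
    for (a in acceptors) {
      if (a == donors$D[i]) next
      dv <- frame$coords[a, ] - D
      dv <- dv - frame$box * round(dv / frame$box)
      if (sqrt(sum(dv^2)) > criteria$max_DA_distance) next
      hv <- H - D
      hv <- hv - frame$box * round(hv / frame$box)
      ct <- sum(hv * dv) / sqrt(sum(hv^2) * sum(dv^2))
      ang <- acos(max(-1, min(1, ct))) * 180 / pi
      if (ang <= criteria$max_HDA_angle) hits <- hits + 1L
    }
  }
  hits
}
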