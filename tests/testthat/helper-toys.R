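# Small synthetic networks used across the unit tests.

# single cell state with logistic growth (and optional death)
toy_logistic <- function() {
  nodes <- node_spec("A", "cell_state")
  edges <- list(
    edge_spec("proliferation", "A", params = c(Kprol = "Kprol_A")),
    edge_spec("death", "A", params = c(KD = "KD_A"))
  )
  network_spec(nodes, edges,
               pools = list(list(members = "A", cap_key = "xmax_A")))
}

toy_logistic_params <- function(Kprol = 1, xmax = 1, KD = 0) {
  c(Kprol_A = Kprol, xmax_A = xmax, KD_A = KD)
}

# pure conversion chain A -> B, no growth or death: conserves A + B
toy_conversion <- function() {
  nodes <- rbind(node_spec("A", "cell_state"), node_spec("B", "cell_state"))
  edges <- list(
    edge_spec("conversion", "B", "A", params = c(Kconv = "Kconv_AB"))
  )
  network_spec(nodes, edges)
}

# perturbed-but-valid registries for property tests
jittered_params <- function(seed) random_parameter_set(seed, spread = 2)
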