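# Seeded random class-expression generator over the fixture
# vocabulary. Atoms are drawn from classes with no equivalence axioms
# (GO / PATO / ChEBI), so the generated expressions stay inside the
# fragment the brute-force oracle covers.

gen_atom_pool <- sort(c(
  names(fx$mini_go$terms), names(fx$mini_pato$terms),
  names(fx$mini_chebi$terms)
))

gen_relation_pool <- relation_vocabulary()$relations

random_expression <- function(depth = 3L, p_atom = 0.35) {
  if (depth <= 0L || stats::runif(1) < p_atom) {
    return(ce_atom(sample(gen_atom_pool, 1L)))
  }
  if (stats::runif(1) < 0.55) {
    return(ce_some(sample(gen_relation_pool, 1L),
                   random_expression(depth - 1L, p_atom)))
  }
  n <- sample(2:3, 1L)
  ops <- lapply(seq_len(n), function(i) {
    random_expression(depth - 1L, p_atom = min(1, p_atom + 0.35))
  })
  # operands may collapse to fewer than two distinct nodes; ce_and
  # requires two, so regenerate atoms if needed
  ce_and(ops)
}
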