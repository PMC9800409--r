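# Prisoner's dilemma, Shafir & Tversky averages: second player's defection
# probability given the first player's known move; prior is the first
# player's (equal-odds) defection probability.
prior_a1: 0.5
p_b1_given_a1: 0.97
p_b1_given_a2: 0.84
labels:
  a: [defect, cooperate]
  b: [defect, cooperate]
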