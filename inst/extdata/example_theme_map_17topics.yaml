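# Example topic->theme map for a 17-topic model: five named work themes,
# with every unassigned topic falling into the implicit "Others" theme.
# Theme grouping is a manual, domain-knowledge step; edit the topic indices
# to match the topics of your own fitted model.
themes:
  Evaluation: [9, 17]
  Courses: [4, 10, 12]
  "Progress tracking": [3, 15]
  "Situation tracking": [1, 7, 13]
  "Final grading": [16]
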