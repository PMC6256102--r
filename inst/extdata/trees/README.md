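# Example dependency trees

Bracketed-dialect trees for two wait-time review sentences used throughout
the documentation and tests:

- `negated_long_wait.tree` — "there are never long wait times", a short-wait
  (`x`) sentence with a negation edge.
- `waiting_room_hour.tree` — "I arrived to my appointment on time and waited
  in his waiting room for over an hour", a long-wait (`y`) sentence.
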