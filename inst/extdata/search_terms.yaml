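# Default screening configuration: search terms applied to the free-text
# clinical note and treatment fields to flag candidate deaths.
# Grammar: bare word = whole-token match; trailing * = prefix match;
# quoted multiword = consecutive-token phrase; "..." ~ k = all phrase words
# within a window allowing up to k intervening tokens, any order;
# ["a" and "b"] = all words anywhere in the field.
screening:
  note_terms:
    - euth
    - "pts*"
    - "crem*"
    - ashes
    - "pento*"
    - casket
    - beech
    - "decease*"
    - death
    - '"put to sleep"'
    - doa
    - died
    - killed
    - '"home bury" ~ 1'
    - '["bury" and "home"]'
  treatment_terms:
    - "euth*"
    - "pento*"
    - "crem*"
    - casket
    - scatter
    - beech
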