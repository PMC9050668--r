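# Compact breed classifier: breeds on the recognised list are treated as
# purebred; recognised breeds missing from the group map fall back to
# "non-KC recognised". Covers the 18 breeds common enough for per-breed
# life tables plus a few extras; real deployments supply a fuller taxonomy.
recognised_breeds:
  - American Bulldog
  - Beagle
  - Border Collie
  - Boxer
  - Cavalier King Charles Spaniel
  - Chihuahua
  - Cocker Spaniel
  - English Bulldog
  - French Bulldog
  - German Shepherd Dog
  - Husky
  - Jack Russell Terrier
  - Labrador Retriever
  - Pug
  - Shih-tzu
  - Springer Spaniel
  - Staffordshire Bull Terrier
  - Yorkshire Terrier
  - Dogue de Bordeaux
  - Miniature Poodle
groups:
  Beagle: Hound
  Border Collie: Pastoral
  Boxer: Working
  Cavalier King Charles Spaniel: Toy
  Chihuahua: Toy
  Cocker Spaniel: Gundog
  English Bulldog: Utility
  French Bulldog: Utility
  German Shepherd Dog: Pastoral
  Husky: Working
  Jack Russell Terrier: Terrier
  Labrador Retriever: Gundog
  Pug: Toy
  Shih-tzu: Utility
  Springer Spaniel: Gundog
  Staffordshire Bull Terrier: Terrier
  Yorkshire Terrier: Toy
  Dogue de Bordeaux: Working
  Miniature Poodle: Utility
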