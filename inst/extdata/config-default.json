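{
  "fields": [
    {"name": "first_name",     "comparator": "dice",   "error_rate": 0.01, "frequency": 0.005,  "bloom_len": 500, "num_hashes": 15},
    {"name": "surname",        "comparator": "dice",   "error_rate": 0.01, "frequency": 0.004,  "bloom_len": 500, "num_hashes": 15},
    {"name": "birth_name",     "comparator": "dice",   "error_rate": 0.05, "frequency": 0.004,  "bloom_len": 500, "num_hashes": 15},
    {"name": "day_of_birth",   "comparator": "binary", "error_rate": 0.02, "frequency": 0.0357},
    {"name": "month_of_birth", "comparator": "binary", "error_rate": 0.02, "frequency": 0.0833},
    {"name": "year_of_birth",  "comparator": "binary", "error_rate": 0.02, "frequency": 0.0143},
    {"name": "zip_code",       "comparator": "binary", "error_rate": 0.03, "frequency": 0.001},
    {"name": "city",           "comparator": "dice",   "error_rate": 0.02, "frequency": 0.01,   "bloom_len": 500, "num_hashes": 15}
  ],
  "exchange_groups": [["first_name", "surname", "birth_name"]],
  "threshold_tentative": 0.7,
  "threshold_match": 0.9,
  "fixedpoint_bits": 16,
  "ring_bits": 48,
  "weight_scale": 64,
  "salt": "epilinkr/v1"
}
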