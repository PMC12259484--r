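[
  {
    "rule_id": "dist_low_frequency",
    "behaviour": "social_distancing",
    "trigger": {"field": "distance_frequency", "op": "le", "value": "sometimes"},
    "priority": 3
  },
  {
    "rule_id": "dist_often",
    "behaviour": "social_distancing",
    "trigger": {"field": "distance_frequency", "op": "eq", "value": "often"},
    "priority": 1
  },
  {
    "rule_id": "iso_visits_friends",
    "behaviour": "self_isolation",
    "trigger": {"field": "isolation_behaviours", "op": "contains", "value": "visit_friends"},
    "priority": 2
  },
  {
    "rule_id": "iso_visits_family",
    "behaviour": "self_isolation",
    "trigger": {"field": "isolation_behaviours", "op": "contains", "value": "visit_family"},
    "priority": 2
  },
  {
    "rule_id": "iso_would_never_isolate",
    "behaviour": "self_isolation",
    "trigger": {"field": "isolation_triggers", "op": "contains", "value": "never"},
    "priority": 3
  },
  {
    "rule_id": "iso_not_mostly_home",
    "behaviour": "self_isolation",
    "trigger": {"field": "isolation_behaviours", "op": "not_contains", "value": "mostly_home"},
    "priority": 1
  },
  {
    "rule_id": "hw_rarely_washes",
    "behaviour": "hand_washing",
    "trigger": {"field": "handwash_situations", "op": "contains", "value": "never_or_occasionally"},
    "priority": 3
  },
  {
    "rule_id": "hw_no_thorough_practice",
    "behaviour": "hand_washing",
    "trigger": {"field": "handwash_thoroughness", "op": "contains", "value": "none_of_above"},
    "priority": 3
  },
  {
    "rule_id": "hw_no_soap",
    "behaviour": "hand_washing",
    "trigger": {"field": "handwash_thoroughness", "op": "not_contains", "value": "soap_or_sanitiser"},
    "priority": 2
  },
  {
    "rule_id": "hw_not_before_food",
    "behaviour": "hand_washing",
    "trigger": {"field": "handwash_situations", "op": "not_contains", "value": "before_food"},
    "priority": 1
  }
]
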