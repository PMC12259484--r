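{
  "exposure": {
    "work_contexts": {
      "patients_vulnerable": 1,
      "children": 1,
      "coworkers": 1,
      "general_public": 1,
      "from_home": 0,
      "not_working": 0
    },
    "isolation_behaviours": {
      "food_medicine_healthcare": 1,
      "outdoor_exercise": 1,
      "other_shops_services": 1,
      "mostly_home": 0,
      "visit_family": 1,
      "visit_friends": 1
    },
    "distance_frequency": {
      "almost_never": 4,
      "rarely": 3,
      "sometimes": 2,
      "often": 1,
      "almost_always": 0,
      "never_in_public": 0
    }
  },
  "exposure_modifiers": {
    "isolation_triggers": {
      "own_symptoms": 0.95,
      "contact_with_sick": 0.95,
      "government_restrictions": 0.95,
      "never": 1,
      "other": 1
    },
    "behaviours_would_stop": {
      "food_medicine_healthcare": 0.99,
      "outdoor_exercise": 0.99,
      "other_shops_services": 0.99,
      "mostly_home": 1,
      "visit_family": 0.99,
      "visit_friends": 0.99,
      "other": 1
    }
  },
  "hygiene": {
    "handwash_situations": {
      "public_surfaces": 0,
      "entering_building": 0,
      "before_food": 0,
      "after_contact": 0,
      "after_sneeze_cough": 0,
      "touching_face": 0,
      "never_or_occasionally": 1
    },
    "handwash_thoroughness": {
      "soap_or_sanitiser": 0,
      "twenty_seconds": 0,
      "nails_and_fingers": 0,
      "none_of_above": 1
    }
  },
  "uncontrollable": {
    "age_band": {
      "under_20": 0,
      "20_29": 0,
      "30_39": 0,
      "40_49": 1,
      "50_59": 1,
      "60_69": 2,
      "70_plus": 3,
      "declined": 1
    },
    "gender": {
      "female": 0,
      "male": 1,
      "nonbinary_or_self_specified": 0,
      "declined": 0
    }
  },
  "factor_scale_max": {
    "exposure": 13,
    "hygiene": 2,
    "uncontrollable": 4
  },
  "cuts": [33, 66]
}
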