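{
  "hyperthyroidism": [
    {"system": "ICD-10-CM", "code": "E05*"},
    {"system": "ICD-9", "code": "242*"}
  ],
  "exophthalmos": [
    {"system": "ICD-10-CM", "code": "H05.20"},
    {"system": "ICD-10-CM", "code": "H05.21*"},
    {"system": "ICD-10-CM", "code": "H05.24*"},
    {"system": "ICD-10-CM", "code": "H05.25*"},
    {"system": "ICD-10-CM", "code": "H05.26*"},
    {"system": "ICD-9", "code": "376.2*"},
    {"system": "ICD-9", "code": "376.30"}
  ],
  "diplopia": [
    {"system": "ICD-10-CM", "code": "H53.2"},
    {"system": "ICD-9", "code": "368.2"}
  ],
  "lid_retraction": [
    {"system": "ICD-10-CM", "code": "H02.53*"},
    {"system": "ICD-9", "code": "374.41"}
  ],
  "strabismus": [
    {"system": "ICD-10-CM", "code": "H49*"},
    {"system": "ICD-10-CM", "code": "H50*"},
    {"system": "ICD-9", "code": "378*"}
  ],
  "orbital_inflammation": [
    {"system": "ICD-10-CM", "code": "H05.0*"},
    {"system": "ICD-10-CM", "code": "H05.1*"},
    {"system": "ICD-9", "code": "376.0*"},
    {"system": "ICD-9", "code": "376.1*"}
  ],
  "ocular_pain": [
    {"system": "ICD-10-CM", "code": "H57.1*"},
    {"system": "ICD-9", "code": "379.91"}
  ],
  "keratoconjunctivitis": [
    {"system": "ICD-10-CM", "code": "H16.2*"},
    {"system": "ICD-9", "code": "370.3*"},
    {"system": "ICD-9", "code": "370.40"}
  ],
  "eye_edema": [
    {"system": "ICD-10-CM", "code": "H02.84*"},
    {"system": "ICD-10-CM", "code": "H11.42*"},
    {"system": "ICD-9", "code": "374.82"},
    {"system": "ICD-9", "code": "372.73"}
  ],
  "visual_disturbance": [
    {"system": "ICD-10-CM", "code": "H53.14*"},
    {"system": "ICD-10-CM", "code": "H53.8"},
    {"system": "ICD-10-CM", "code": "H53.9"},
    {"system": "ICD-9", "code": "368.8"},
    {"system": "ICD-9", "code": "368.9"}
  ],
  "scotoma": [
    {"system": "ICD-10-CM", "code": "H53.4*"},
    {"system": "ICD-9", "code": "368.4*"}
  ],
  "vision_deficiency": [
    {"system": "ICD-10-CM", "code": "H54*"},
    {"system": "ICD-9", "code": "369*"}
  ],
  "corneal_ulcer": [
    {"system": "ICD-10-CM", "code": "H16.0*"},
    {"system": "ICD-9", "code": "370.0*"}
  ],
  "optic_neuropathy": [
    {"system": "ICD-10-CM", "code": "H46*"},
    {"system": "ICD-10-CM", "code": "H47.0*"},
    {"system": "ICD-9", "code": "377.3*"}
  ],
  "periorbital_edema": [
    {"system": "ICD-10-CM", "code": "H05.22*"},
    {"system": "ICD-9", "code": "376.33"}
  ],
  "eyelid_erythema": [
    {"system": "ICD-10-CM", "code": "H01.8*"},
    {"system": "ICD-9", "code": "373.8*"}
  ]
}
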