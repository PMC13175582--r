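{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "sepsiscues interface payload",
  "description": "One assembled decision-support interface for a single patient state. Cue composition per interface is enforced by sepsiscues::validate_payload(): case_features {R1,R2}; treatment_risk/mortality_risk {R3}; interactive_treatment_risk/interactive_mortality_risk {R7,R3,R4,R5} plus optional R8; prior_clinician_actions {R7,R5,R6}; treatment_recommendation {R7,R8}.",
  "type": "object",
  "required": ["interface_name", "patient_id", "bin_index", "cues"],
  "properties": {
    "interface_name": {
      "enum": ["case_features", "treatment_risk", "mortality_risk",
               "interactive_treatment_risk", "interactive_mortality_risk",
               "prior_clinician_actions", "treatment_recommendation"]
    },
    "patient_id": { "type": "string" },
    "bin_index": { "type": "integer", "minimum": 0 },
    "selected_plan": { "$ref": "#/$defs/plan" },
    "k_actual": { "type": "integer", "minimum": 1 },
    "cues": {
      "type": "array",
      "items": { "$ref": "#/$defs/cue" }
    },
    "no_recommendation": { "type": "boolean" },
    "plan_support": {
      "type": "object",
      "properties": {
        "n_plan": { "type": "integer" },
        "sufficient": { "type": "boolean" }
      }
    },
    "modal_plan": {
      "type": "object",
      "description": "Implicit peer recommendation of prior_clinician_actions",
      "properties": {
        "volume_action": { "$ref": "#/$defs/volume_action" },
        "pressor_action": { "$ref": "#/$defs/pressor_action" },
        "implicit": { "const": true }
      }
    }
  },
  "$defs": {
    "volume_action": { "enum": ["give_fluids", "none", "give_diuretics"] },
    "pressor_action": { "enum": ["increase_or_start", "maintain", "decrease_or_stop"] },
    "plan": {
      "type": ["object", "null"],
      "required": ["volume_action", "pressor_action"],
      "properties": {
        "volume_action": { "$ref": "#/$defs/volume_action" },
        "pressor_action": { "$ref": "#/$defs/pressor_action" }
      }
    },
    "cue": {
      "type": "object",
      "required": ["cue_code", "version", "inputs_digest", "payload"],
      "properties": {
        "cue_code": {
          "pattern": "^R[1-8](-(L|M|H|Y|N))?$"
        },
        "version": { "type": "string" },
        "inputs_digest": { "pattern": "^[0-9a-f]{8}$" },
        "payload": { "type": "object" }
      }
    }
  }
}
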