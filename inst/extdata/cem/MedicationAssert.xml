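<cetype kind="statement" name="MedicationAssert" xmlns="">
  <key code="Assertion_KEY_ECID" />
  <data domain="MedicationType_VALUESET_ECID" type="cwe" />
  <qual card="0-1" name="strength" type="Strength" />
  <qual card="0-1" name="dosage" type="Dosage" />
  <qual card="0-1" name="duration" type="Duration" />
  <qual card="0-1" name="form" type="Form" />
  <qual card="0-1" name="frequency" type="Frequency" />
  <qual card="0-1" name="route" type="Route" />
  <qual card="0-1" name="statusChange" type="StatusChange" />
  <mod card="0-1" name="subject" type="Subject" />
  <mod card="0-1" name="negationInd" type="NegationInd" />
  <mod card="0-1" name="uncertainty" type="Uncertainty" />
  <att card="0-1" name="observed" type="Observed" />
  <att card="0-1" name="reportedReceived" type="ReportedReceived" />
  <att card="0-1" name="verified" type="Verified" />
</cetype>
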