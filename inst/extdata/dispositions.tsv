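disposition	chebi_role
non-activating competitive beta-adrenergic receptor binding disposition	beta-adrenergic antagonist
function-inhibiting hydrogen/potassium adenosine triphosphatase enzyme (H+/K+ ATPase) binding disposition	proton pump inhibitor
function-inhibiting L-type voltage-gated calcium channel binding disposition	calcium channel blocker
function-inhibiting vitamin K epoxide reductase binding disposition	
function-inhibiting Na-K-Cl cotransporter 2 (NKCC2) binding disposition	
function-inhibiting T-type voltage-gated calcium channel binding disposition	
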