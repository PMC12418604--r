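code,level,label
F10.0,1,Acute alcohol intoxication
T51.0,1,Toxic effect of ethanol
T51.9,1,Toxic effect of alcohol unspecified
F10.1,2,Harmful alcohol use
F10.2,3,Alcohol dependence
F10.3,4,Alcohol withdrawal state
F10.4,4,Alcohol withdrawal state with delirium
K70.0,5,Alcoholic fatty liver
K70.1,5,Alcoholic hepatitis
K70.2,5,Alcoholic fibrosis and sclerosis of liver
K70.3,5,Alcoholic cirrhosis of liver
K70.4,5,Alcoholic hepatic failure
K70.9,5,Alcoholic liver disease unspecified
K85.2,5,Alcohol-induced acute pancreatitis
K85.20,5,Alcohol-induced acute pancreatitis without necrosis or infection
K86.0,5,Alcohol-induced chronic pancreatitis
F10.5,5,Alcohol-induced psychotic disorder
F10.6,5,Alcohol-induced amnesic syndrome
F10.7,5,Alcohol-induced residual and late-onset psychotic disorder
F10.8,5,Other alcohol-induced mental and behavioural disorders
F10.9,5,Alcohol-induced mental and behavioural disorder unspecified
E24.4,5,Alcohol-induced pseudo-Cushing syndrome
G31.2,5,Degeneration of nervous system due to alcohol
G62.1,5,Alcoholic polyneuropathy
G72.1,5,Alcoholic myopathy
I42.6,5,Alcoholic cardiomyopathy
K29.2,5,Alcoholic gastritis
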